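stack	dH_cal_mol	dS_cal_molK	source
AU.AU	-6820	-19.0	Xia1998 RNA/RNA 1M NaCl, 5'AA3'/3'UU5'
AU.UA	-9380	-26.7	Xia1998 RNA/RNA 1M NaCl, 5'AU3'/3'UA5'
UA.AU	-7690	-20.5	Xia1998 RNA/RNA 1M NaCl, 5'UA3'/3'AU5'
CG.UA	-10480	-27.1	Xia1998 RNA/RNA 1M NaCl, 5'CU3'/3'GA5'
CG.AU	-10440	-26.9	Xia1998 RNA/RNA 1M NaCl, 5'CA3'/3'GU5'
GC.UA	-11400	-29.5	Xia1998 RNA/RNA 1M NaCl, 5'GU3'/3'CA5'
GC.AU	-12440	-32.5	Xia1998 RNA/RNA 1M NaCl, 5'GA3'/3'CU5'
CG.GC	-10640	-26.7	Xia1998 RNA/RNA 1M NaCl, 5'CG3'/3'GC5'
GC.GC	-13390	-32.7	Xia1998 RNA/RNA 1M NaCl, 5'GG3'/3'CC5'
GC.CG	-14880	-36.9	Xia1998 RNA/RNA 1M NaCl, 5'GC3'/3'CG5'
init	3610	-1.5	Xia1998 duplex initiation
term_AU	3720	10.5	Xia1998 per terminal A:U pair
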