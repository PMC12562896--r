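group	Pn	He	Ho	Pi	PIC
XWHY	0.5975	0.2714	0.2766	0.2760	0.1661
HY	0.638	0.2608	0.2588	0.2655	0.1725
ZY	0.6399	0.2489	0.2427	0.2533	0.1731
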