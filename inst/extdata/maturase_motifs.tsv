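domain	order	motif
RT	1	LQGWYADDL
X	2	GRKVNPEKSAV
En	3	HRKGLWENWA
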