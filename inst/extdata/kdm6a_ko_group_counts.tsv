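cross	group	n
BC	A	109
BC	B	58
BC	C	27
BC	D	68
BC	E	71
BC	F	50
CB	A	133
CB	B	104
CB	C	32
CB	D	109
CB	E	62
CB	F	27
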