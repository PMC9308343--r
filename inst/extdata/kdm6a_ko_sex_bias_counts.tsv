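cross	sex	n_wt	n_lost	n_gained
BC	female	2048	708	97
BC	male	868	214	24
CB	female	285	90	NA
CB	male	323	77	NA
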