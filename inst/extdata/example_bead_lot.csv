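"peak","pe_per_bead"
1,500
2,5000
3,50000
4,5e+05
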