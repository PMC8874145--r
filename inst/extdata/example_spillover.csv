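"channel","PE","CD3"
"PE",1,0.1
"CD3",0.05,1
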