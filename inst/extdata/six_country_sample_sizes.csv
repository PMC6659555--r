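country,sample_size
Germany,1003
Greece,1000
Hungary,1000
Poland,1006
Romania,1001
Spain,1001
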