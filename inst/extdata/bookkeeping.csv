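item,count
identified,7567
truncated,1383
analyzed,6184
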