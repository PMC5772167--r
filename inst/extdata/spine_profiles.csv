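category,count
one_AS,4246
one_SS,58
two_AS,146
one_AS_one_SS,84
two_AS_one_SS,9
three_AS,6
two_SS,6
three_SS,2
one_AS_two_SS,1
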