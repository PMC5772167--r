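group,percent
all,58.98
AS,59.93
SS,56.90
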