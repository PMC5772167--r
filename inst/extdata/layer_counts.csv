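layer,AS_head,AS_neck,AS_shaft,SS_head,SS_neck,SS_shaft,density_AS,density_SS
I,425,7,92,15,9,51,0.73,0.10
II,814,11,86,7,6,44,1.05,0.08
III,1671,43,300,18,6,146,0.86,0.08
IV,858,27,186,52,7,97,1.02,0.14
V,477,10,113,6,3,47,0.76,0.07
VI,381,10,99,14,4,42,0.40,0.06
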