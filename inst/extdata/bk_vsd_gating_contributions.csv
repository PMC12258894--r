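label,residue_id,helix,q,dq,error
D153,153,S2,-1,0.08,0.04
R167,167,S2,1,0.002,0.03
D186,186,S3,-1,-0.01,0.03
R207,207,S4,1,0.04,0.01
R210,210,S4,1,0.25,0.02
R213,213,S4,1,0.19,0.01
E219,219,S4,-1,-0.09,0.02
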