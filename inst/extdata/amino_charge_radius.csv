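residue_name,atom_name,charge,radius
ARG,CZ,1,1.70
ASP,CG,-1,1.70
GLU,CD,-1,1.70
LYS,NZ,1,1.55
HIS,CE1,0,1.70
ALA,CA,0,1.70
ALA,CB,0,1.70
GLY,CA,0,1.70
TIP,OH2,0,1.52
HOH,O,0,1.52
K,K,1,2.75
CLA,CLA,-1,1.75
POT,POT,1,2.75
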