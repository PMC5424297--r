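# reactant stoichiometry A: R1 = X1 + X2 -> X3, R2 = X3 -> X1 + X2
1 1 0
0 0 1
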