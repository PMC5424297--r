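# initial concentrations of X1, X2, X3
1 0.5 2
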