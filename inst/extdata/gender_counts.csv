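sex,AD,aMCI,SCD,NC
M,12,30,16,21
F,22,37,26,33
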