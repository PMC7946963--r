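id	position
CCPG1_FIR2	104
OPTN_LIR	177
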