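>CCPG1_FIR2/99-113 human CCPG1 FIR2 region
TASDDSDIVTLEPPK
>OPTN_LIR/173-185 human Optineurin LIR region
SSEDSFVEIRMAE
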