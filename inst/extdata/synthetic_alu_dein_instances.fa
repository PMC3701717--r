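>synthetic_alu_dein_1
CACGCCTGTAATCCCACCACCTTGG
>synthetic_alu_dein_2
CACGCCTTTAATCCCATCACTTTGG
>synthetic_alu_dein_3
CACGCCCGTAATCCCAGCACTTTGG
>synthetic_alu_dein_4
CACGCGTGTAATCCCAGCACTTTGG
>synthetic_alu_dein_5
CACGCCTGTAATCCCAGCACTTAGG
>synthetic_alu_dein_6
CACGCCTGTAATCCCTGCACTTTGG
>synthetic_alu_dein_7
CACGCCTGTAATCCCAGCAGTTTGG
>synthetic_alu_dein_8
CACCCCTGTAATCTCAGCACTTTGG
>synthetic_alu_dein_9
AACGCCTGTAATCCCAGCACTTTGG
>synthetic_alu_dein_10
CACGCCTGTAATCCCAGCACTTTGG
>synthetic_alu_dein_11
CTCGCCTGTAATCCCAGCACTTTGG
>synthetic_alu_dein_12
CACGCCTGCAGTCCCAGCACTTTGG
>synthetic_alu_dein_13
CACGCCTGAAATCTCAGCACTTTGG
>synthetic_alu_dein_14
CACGCCTGTAATCCCAGCACTGTGG
>synthetic_alu_dein_15
CACGCCTGTAATCCCAGCACTTTGG
>synthetic_alu_dein_16
CACGCCTGTAATCCCAGCATTTTGG
>synthetic_alu_dein_17
CACGCCTGTAATCCCACAACTTTGG
>synthetic_alu_dein_18
CACGCTTGTAATCCCATCACTTTGG
>synthetic_alu_dein_19
CACGCCTTTAATCCCAGCACTTTGG
>synthetic_alu_dein_20
CACGCCTGTAATCCCAGCACTTTGG
>synthetic_alu_dein_21
CACGCCTGTAAGCCCAGCACTTTGG
>synthetic_alu_dein_22
CACGCCTGTAATCCCAGCACTTTGG
>synthetic_alu_dein_23
CACGCCTGCAATCCCAGCACTTTGT
>synthetic_alu_dein_24
CACGCCTGTAATCCCAGAACTTTGG
>synthetic_alu_dein_25
TACGCCTGTAAGCCCAGCACTTTGG
>synthetic_alu_dein_26
CACGCCTGTAATCCCAGCACTTTGG
>synthetic_alu_dein_27
CACGCCTGTGATCGCAGCACTTTGG
>synthetic_alu_dein_28
CACGCCTGTAATCCCAGCACTTTGG
>synthetic_alu_dein_29
CACGCCTGTAATCCCAGCTCTTTGG
>synthetic_alu_dein_30
CACGCCTGTAATCCCAGCACTTTGG
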