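gene	regulon
gA1	crpR
gA2	crpR
gB1	crpR
gB1	arcR
gB2	arcR
gB3	arcR
gC1	oxR
gD1	oxR
gD2	oxR
gE1	oxR
gE1	crpR
gF1	bioR
gF2	bioR
gG1	glpR
gG2	glpR
gG3	glpR
gG4	glpR
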