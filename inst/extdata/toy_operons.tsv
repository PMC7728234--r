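gene	operon
gA1	opA
gA2	opA
gB1	opB
gB2	opB
gB3	opB
gC1	opC
gD1	opD
gD2	opD
gE1	opE
gF1	opF
gF2	opF
gG1	opG1
gG2	opG2
gG3	opG2
gG4	opG3
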