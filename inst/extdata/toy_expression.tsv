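gene	strain	change
gA1	producer	up
gA2	producer	up
gB1	producer	down
gB2	producer	unchanged
gB3	producer	down
gC1	producer	up
gD1	producer	up
gD2	producer	unchanged
gE1	producer	unchanged
gF1	producer	unchanged
gF2	producer	unchanged
gG1	producer	unchanged
gG2	producer	unchanged
gG3	producer	unchanged
gG4	producer	unchanged
gA1	consumer	down
gA2	consumer	down
gB1	consumer	up
gB2	consumer	up
gB3	consumer	unchanged
gC1	consumer	unchanged
gD1	consumer	up
gD2	consumer	up
gE1	consumer	up
gF1	consumer	unchanged
gF2	consumer	unchanged
gG1	consumer	unchanged
gG2	consumer	unchanged
gG3	consumer	unchanged
gG4	consumer	unchanged
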