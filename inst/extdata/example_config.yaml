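# Example configuration for run_config(): scan the bundled core fixture's
# two by-products under ROOM and rank them.
model: core_fixture
method: room
beta: 0.001
seed: 1
metabolites:
  - EX_ace_e
  - EX_glyc_e
tasks:
  - ancestor
  - scan
  - rank
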