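# Example structure-pipeline configuration: Monte Carlo ensemble of a small
# four-loop rosette, contact map, and loop-base calls.
seed: 15
chain:
  config: "lin(100) - dom(600)[loop(150) - loop(150) - loop(150) - loop(150)] - lin(100)"
  n: 25
map:
  bin_size: 2500
  diag_mask: 30000
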