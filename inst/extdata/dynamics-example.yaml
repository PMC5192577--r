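# Example dynamics-pipeline configuration: synthetic bound-emitter traces
# at the open-chromatin relaxation time, analysed by the full
# correlate -> window-scan -> relaxation-fit chain.
seed: 16
fcs:
  w_0: 200
  z_0: 1000
  topology: loop_rosette
  solvent: theta
  window_grid: [1, 2, 5, 10]
synth:
  tau_1: 0.161
  duration: 30
  n_traces: 1
  p_max: 6
  n_emitters: 300
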