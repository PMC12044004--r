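# Demonstration pipeline configuration: a small two-pair simulation run
# end-to-end (simulate -> qc -> diversity -> structure -> topology).
seed: 1
out_dir: foniokit_demo
stages:
  simulate: true
  qc: true
  diversity: true
  kmers: true
  structure: true
  topology: true
  demography: false
simulate:
  n_windows: 30
  window_len: 50000
  samples:
    exilis: 6
    longiflora: 4
    iburua: 6
    ternata: 4
  model: two_pair_bottleneck
structure:
  K: 2
  n_runs: 3
kmers:
  k: 21
  n_tables: 10
  table_size: 1000
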