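# default study-calibrated synthetic run
input:
  generator:
    seed: 42
level: component
node_freq_min: 0.10
edge_occ_min: 10
focal_edge_occ_min: 2
focal_types:
  - type_nha_01
freq_cut: median
rank_cut: median
rank_mode: raw
retain: 0.8
k: auto
test: student
n_permutations: 100
seed: 42
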