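# Example run configuration: a scaled-down 22-h induction protocol of the
# GAL network. Unset keys take the package defaults (see load_config()).
seed: 1
protocol:
  id: 22h
  galactose: 0.05
  n_initial: 40
  t_pre: 330
  n_sample: 40
  t_post: 330
  snapshot_interval: 10
network:
  noise_cv: 0.10
cell_cycle:
  c_inherit: 0.25
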