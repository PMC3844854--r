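# Example simulation configuration (all fields optional; defaults shown by
# dump_config(network_config())).
n_gp: 100
n_stn: 50
gp_fanout: 20
stn_fanout: 2
condition: parkinsonian
duration: 13000
seed: 1
downregulation:
  T_HCN: 0.2
  k_HCN: 0.6
  theta: 0.5
  sigma: 0.1
  update_interval: 1.0
  enabled: true
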