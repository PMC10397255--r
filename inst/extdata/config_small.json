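{
  "design": {
    "standard_numerosities": [12, 24],
    "conditions": ["symmetry", "random"],
    "tasks": ["ST", "DT"],
    "sessions_per_cell": 1,
    "trials_per_session": 20,
    "n_participants": 4,
    "seed": 20230801
  },
  "population": {
    "b_sym_mean": {"ST": 0.9213, "ST_WD": 0.936, "DT": 0.97},
    "s_mean": {"ST": 0.2096, "ST_WD": 0.2096, "DT": 0.3984}
  },
  "master_seed": 20230801
}
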