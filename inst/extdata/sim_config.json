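{
  "universe_size": 2000,
  "core_size": 700,
  "gain_rate": 0.105,
  "loss_rate": 0.195,
  "root_presence_prob": 0.35,
  "birth_rate": 1.0,
  "families_per_reaction": 1,
  "n_nonmetabolic": 1000,
  "n_substrates": 32,
  "reactions_per_trait": 3,
  "flip_noise": 0.3,
  "missing_prob": 0.01,
  "n_clades": 8
}
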