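{
  "comment": "SYNTHETIC top-scoring-pairs model for testing the classifier plumbing. Pairs, weights and intercept are illustrative, not the published subtype classifier coefficients; load those from their public release for production calls.",
  "version": "synthetic-1",
  "pairs": [
    ["GPR87", "REG4"],
    ["KRT6A", "ANXA10"],
    ["BCAR3", "GATA6"],
    ["PTGES", "CLDN18"],
    ["ITGA3", "LGALS4"],
    ["C16orf74", "DDC"],
    ["S100A2", "SLC40A1"],
    ["KRT5", "CLRN3"]
  ],
  "weights": [1.2, 1.0, 0.9, 0.8, 0.8, 0.7, 0.6, 0.5],
  "intercept": -3.2,
  "threshold": 0.5
}
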