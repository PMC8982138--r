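{
  "provenance": "hand-computed arithmetic on the stored tables",
  "expected": {
    "scaling_factor": [2.0, 1.0],
    "M": [30, 10],
    "naive_mu_hat_s1": [10, 20, 30]
  }
}
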