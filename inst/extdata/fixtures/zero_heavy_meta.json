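{
  "provenance": "hand-built sparse table; 14 of 20 counts are zero",
  "expected": { "zero_fraction": 0.7 }
}
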