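{
  "provenance": "degenerate single-category community; M equals W",
  "expected": { "M": [3] }
}
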