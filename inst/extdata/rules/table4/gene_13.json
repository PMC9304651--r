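{
  "gene": 13,
  "output_oscillator": 3,
  "responsive": [1, 3, 4, 5, 9, 10],
  "nonresponsive": [0, 2, 6, 7, 8],
  "fallback": 0,
  "published_accuracy_percent": 71.1
}
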