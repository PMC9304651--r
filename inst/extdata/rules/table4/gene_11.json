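{
  "gene": 11,
  "output_oscillator": 2,
  "responsive": [1, 2, 6, 7, 11],
  "nonresponsive": [3, 4, 5, 8, 9, 10],
  "fallback": 0,
  "published_accuracy_percent": 69.8
}
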