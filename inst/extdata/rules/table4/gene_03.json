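{
  "gene": 3,
  "output_oscillator": 1,
  "responsive": [2, 6, 7, 8, 9, 11],
  "nonresponsive": [1, 3, 4, 5, 10],
  "fallback": 0,
  "published_accuracy_percent": 68.2
}
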