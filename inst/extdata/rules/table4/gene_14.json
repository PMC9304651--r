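{
  "gene": 14,
  "output_oscillator": 3,
  "responsive": [0, 1, 2, 4, 7],
  "nonresponsive": [3, 5, 6, 8, 9, 10, 11],
  "fallback": 0,
  "published_accuracy_percent": 68.2
}
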