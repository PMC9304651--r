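{
  "gene": 8,
  "output_oscillator": 1,
  "responsive": [0, 2, 4, 6, 7, 8, 9],
  "nonresponsive": [1, 3, 5, 10],
  "fallback": 0,
  "published_accuracy_percent": 69.4
}
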