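{
  "gene": 6,
  "output_oscillator": 1,
  "responsive": [2, 5, 6],
  "nonresponsive": [0, 1, 3, 4, 7, 8, 9],
  "fallback": 0,
  "published_accuracy_percent": 67.7
}
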