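{
  "gene": 4,
  "output_oscillator": 1,
  "responsive": [1, 2, 3, 4, 7, 9],
  "nonresponsive": [0, 5, 6, 8],
  "fallback": 0,
  "published_accuracy_percent": 67.7
}
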