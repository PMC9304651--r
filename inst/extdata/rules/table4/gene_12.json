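{
  "gene": 12,
  "output_oscillator": 1,
  "responsive": [2, 3],
  "nonresponsive": [1, 3, 4, 5, 6, 7, 8],
  "fallback": 0,
  "published_accuracy_percent": 69.8,
  "conflict": 3
}
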