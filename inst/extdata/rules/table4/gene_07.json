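{
  "gene": 7,
  "output_oscillator": 2,
  "responsive": [2, 6, 9],
  "nonresponsive": [1, 3, 4, 5, 7, 8, 10, 11],
  "fallback": 0,
  "published_accuracy_percent": 69
}
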