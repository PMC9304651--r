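{
  "gene": 2,
  "output_oscillator": 1,
  "responsive": [3, 6, 7, 9, 10],
  "nonresponsive": [1, 2, 4, 5, 8, 11],
  "fallback": 0,
  "published_accuracy_percent": 60
}
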