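{
  "gene": 10,
  "output_oscillator": 3,
  "responsive": [1, 3, 6, 7, 10],
  "nonresponsive": [2, 4, 5, 8, 9, 11],
  "fallback": 0,
  "published_accuracy_percent": 66.5
}
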