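{
  "gene": 5,
  "output_oscillator": 3,
  "responsive": [1, 5, 7, 9],
  "nonresponsive": [3, 4, 6, 8, 10, 11],
  "fallback": 0,
  "published_accuracy_percent": 68.2
}
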