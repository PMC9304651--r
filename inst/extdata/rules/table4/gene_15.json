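{
  "gene": 15,
  "output_oscillator": 3,
  "responsive": [3, 4],
  "nonresponsive": [1, 2, 5, 6, 7, 8, 10],
  "fallback": 0,
  "published_accuracy_percent": 69.4
}
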