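{
  "gene": 9,
  "output_oscillator": 3,
  "responsive": [0, 2, 3, 5, 7, 8],
  "nonresponsive": [1, 4, 6, 9, 10],
  "fallback": 0,
  "published_accuracy_percent": 66.5
}
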