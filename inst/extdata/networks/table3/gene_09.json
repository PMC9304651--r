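{
  "gene": 9,
  "m": 3,
  "t_max": 74.63,
  "t_start": 2.49,
  "t_end": 28.12,
  "alpha": 0.7,
  "beta": 0.08,
  "input_oscillators": [1, 2],
  "normal_oscillators": 3,
  "t_illum": {
    "3": 10.56
  },
  "output_oscillator": 3
}
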