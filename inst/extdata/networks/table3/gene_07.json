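{
  "gene": 7,
  "m": 3,
  "t_max": 80,
  "t_start": 1.87,
  "t_end": 69.8,
  "alpha": 0.63,
  "beta": 0.06,
  "input_oscillators": 1,
  "normal_oscillators": [2, 3],
  "t_illum": {
    "2": 3.51,
    "3": 5.28
  },
  "output_oscillator": 2
}
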