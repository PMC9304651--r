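{
  "gene": 11,
  "m": 3,
  "t_max": 80,
  "t_start": 2.74,
  "t_end": 29.05,
  "alpha": 0.69,
  "beta": 0.07,
  "input_oscillators": 1,
  "normal_oscillators": [2, 3],
  "t_illum": {
    "2": 3.16,
    "3": 7.25
  },
  "output_oscillator": 2
}
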