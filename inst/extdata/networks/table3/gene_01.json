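{
  "gene": 1,
  "m": 3,
  "t_max": 77.35,
  "t_start": 28.11,
  "t_end": 2.31,
  "alpha": 0.69,
  "beta": 0.08,
  "input_oscillators": 1,
  "normal_oscillators": [2, 3],
  "t_illum": {
    "2": 17.63,
    "3": 7.24
  },
  "output_oscillator": 2
}
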