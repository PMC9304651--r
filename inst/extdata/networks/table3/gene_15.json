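{
  "gene": 15,
  "m": 3,
  "t_max": 75.71,
  "t_start": 62.57,
  "t_end": 3.52,
  "alpha": 0.66,
  "beta": 0.08,
  "input_oscillators": [1, 2],
  "normal_oscillators": 3,
  "t_illum": {
    "3": 0.78
  },
  "output_oscillator": 3
}
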