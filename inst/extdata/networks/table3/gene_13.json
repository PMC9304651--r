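{
  "gene": 13,
  "m": 3,
  "t_max": 80,
  "t_start": 2.48,
  "t_end": 51.09,
  "alpha": 0.7,
  "beta": 0.07,
  "input_oscillators": [1, 2],
  "normal_oscillators": 3,
  "t_illum": {
    "3": 2
  },
  "output_oscillator": 3
}
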