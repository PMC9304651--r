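{
  "gene": 12,
  "m": 3,
  "t_max": 70.79,
  "t_start": 70.65,
  "t_end": 1.57,
  "alpha": 0.59,
  "beta": 0.09,
  "input_oscillators": [1, 2],
  "normal_oscillators": 3,
  "t_illum": {
    "3": 13.42
  },
  "output_oscillator": 1
}
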