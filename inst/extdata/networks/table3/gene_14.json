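{
  "gene": 14,
  "m": 3,
  "t_max": 80,
  "t_start": 36.28,
  "t_end": 2.79,
  "alpha": 0.7,
  "beta": 0.08,
  "input_oscillators": [1, 2],
  "normal_oscillators": 3,
  "t_illum": {
    "3": 4.39
  },
  "output_oscillator": 3
}
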