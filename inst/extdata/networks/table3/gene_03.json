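{
  "gene": 3,
  "m": 3,
  "t_max": 80,
  "t_start": 63.81,
  "t_end": 2.26,
  "alpha": 0.7,
  "beta": 0.08,
  "input_oscillators": [1, 2],
  "normal_oscillators": 3,
  "t_illum": {
    "3": 8.58
  },
  "output_oscillator": 1
}
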