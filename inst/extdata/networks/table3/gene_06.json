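{
  "gene": 6,
  "m": 3,
  "t_max": 80,
  "t_start": 2.1,
  "t_end": 42.37,
  "alpha": 0.7,
  "beta": 0.09,
  "input_oscillators": 1,
  "normal_oscillators": [2, 3],
  "t_illum": {
    "2": 2.58,
    "3": 12.11
  },
  "output_oscillator": 1
}
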