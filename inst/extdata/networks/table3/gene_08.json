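{
  "gene": 8,
  "m": 3,
  "t_max": 70.3,
  "t_start": 1.82,
  "t_end": 32.68,
  "alpha": 0.7,
  "beta": 0.081,
  "input_oscillators": 1,
  "normal_oscillators": [2, 3],
  "t_illum": {
    "2": 2.64,
    "3": 10.68
  },
  "output_oscillator": 1
}
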