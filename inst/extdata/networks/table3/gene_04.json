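{
  "gene": 4,
  "m": 3,
  "t_max": 77.45,
  "t_start": 6.02,
  "t_end": 35.37,
  "alpha": 0.68,
  "beta": 0.074,
  "input_oscillators": 1,
  "normal_oscillators": [2, 3],
  "t_illum": {
    "2": 8.26,
    "3": 2.84
  },
  "output_oscillator": 1
}
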