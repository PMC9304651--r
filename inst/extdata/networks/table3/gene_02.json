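{
  "gene": 2,
  "m": 3,
  "t_max": 77.55,
  "t_start": 2.03,
  "t_end": 33.77,
  "alpha": 0.7,
  "beta": 0.07,
  "input_oscillators": 1,
  "normal_oscillators": [2, 3],
  "t_illum": {
    "2": 8.73,
    "3": 4.33
  },
  "output_oscillator": 1
}
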