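{
  "b": 3.25,
  "k_g": 7.5,
  "k_o": 0,
  "c1": 0.4,
  "c2": 0.4,
  "c3": 6.5,
  "c4": 0.8,
  "tau": 0.5,
  "dt": 0.01
}
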