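{
  "positions_right": [
    20,
    36,
    48,
    36,
    20
  ],
  "positions_left": [
    -20,
    -36,
    -48,
    -36,
    -20
  ],
  "x5th_meta": 48,
  "labels": [
    "big_toe",
    "met1",
    "met5",
    "cuboid",
    "heel"
  ]
}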