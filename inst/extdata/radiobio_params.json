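{
  "structure": ["ptv", "brainstem", "cord", "lung", "heart"],
  "kind": ["tumor", "normal", "normal", "normal", "normal"],
  "a": [-13, 7, 13, 1, 3],
  "d50": [49.09, 65, 66.5, 24.5, 48],
  "gamma50": [2.16, 3, 3, 2, 3],
  "slope50": [4.14, null, null, null, null]
}
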