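schema_version: 1
M:
  offset: -8.4858815
  amplitude: 83.0618021
  midpoint: 62.7985564
  scale: 12.8839771
T:
  offset: 505.2079252
  amplitude: -385.0262831
  midpoint: 23.9877868
  scale: 6.8535623
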