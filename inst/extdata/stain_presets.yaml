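# Stain absorbance presets (RGB optical-density triples, one row per stain).
# version: 1
hdab:
  hematoxylin: [0.650, 0.704, 0.286]
  eosin: [0.072, 0.990, 0.105]
  dab: [0.268, 0.570, 0.776]
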