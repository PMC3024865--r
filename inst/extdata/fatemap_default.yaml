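# Designated structure of the default embryogenesis fate map.
# Super-nodes are the terminal "neighbor tissue" groups; the three germ
# layers partition the 24 leaf tissues.
germ_layer_nodes:
  - Ectoderm
  - Mesoderm
  - Endoderm
super_nodes:
  - PrimitiveGut1
  - PrimitiveGut2
  - PrimitiveGut3
  - ParaxialMesoderm
  - KU
  - Gonad
  - LateralPlateMesoderm
  - NeuralCrest
  - Brain1
  - Brain2
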