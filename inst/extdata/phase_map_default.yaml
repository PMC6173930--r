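# Published stage grouping for the opossum/mouse lung development comparison:
# species -> phase -> age labels. Monodelphis ages are postnatal days; mouse
# ages are embryonic (E) or postnatal (P) days.
monodelphis:
  early: [D3, D8, D14]
  intermediate: [D29, D35]
  late: [D63, ADULT]
mouse:
  early: [E16, E16.5, E17, E17.5, E18, E18.5]
  intermediate: [P2, P3, P5, P10, P13]
  late: [P14, P30, P56]
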