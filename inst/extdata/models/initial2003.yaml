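name: initial2003
anchor_window: [1, 50]
required: [PAS, CS]
optional: [USE, UGUA, DSE, AuxDSE]
windows:
  USE->PAS: {min: 5, max: 30, metric: gap}
  UGUA->PAS: {min: 0, max: 8, metric: start}
  PAS->CS: {min: 12, max: 42, metric: gap}
  CS->DSE: {min: 4, max: 40, metric: gap}
  DSE->AuxDSE: {min: 1, max: 100, metric: gap}
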