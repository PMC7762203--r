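name: improved2020
anchor_window: [-12, 7]
required: [PAS, CS]
optional: [USE, UGUA, DSE, AuxDSE]
windows:
  USE->PAS: {min: 5, max: 30, metric: gap}
  UGUA->PAS: {min: 0, max: 8, metric: start}
  PAS->CS: {min: 0, max: 75, metric: gap}
  PAS->DSE: {min: 21, max: 29, metric: gap}
  CS->DSE: {min: 0, max: 50, metric: gap}
  DSE->AuxDSE: {min: 1, max: 100, metric: gap}
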