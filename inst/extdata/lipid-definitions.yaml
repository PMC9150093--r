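DPPC:
  category: PC
  head_atom: P
  scheme: midpoint_tail
  midpoint_atoms:
  - P
  - C2
  tail_atoms:
  - C14
  - C15
  - C16
  - C24
  - C25
  - C26
  anchor_atoms: []
  ch_pairs:
  - - C14
    - H14
  - - C15
    - H15
  - - C16
    - H16
  density_anchor: P
POPC:
  category: PC
  head_atom: P
  scheme: midpoint_tail
  midpoint_atoms:
  - P
  - C2
  tail_atoms:
  - C14
  - C15
  - C16
  - C24
  - C25
  - C26
  anchor_atoms: []
  ch_pairs:
  - - C14
    - H14
  - - C15
    - H15
  - - C16
    - H16
  density_anchor: P
PSM:
  category: SM
  head_atom: P
  scheme: midpoint_tail
  midpoint_atoms:
  - P
  - C2
  tail_atoms:
  - C14
  - C15
  - C16
  - C24
  - C25
  - C26
  anchor_atoms: []
  ch_pairs:
  - - C14
    - H14
  - - C15
    - H15
  - - C16
    - H16
  density_anchor: P
CHL1:
  category: cholesterol
  head_atom: O3
  scheme: two_atom
  midpoint_atoms:
  - P
  - C2
  tail_atoms: []
  anchor_atoms:
  - C3
  - C17
  ch_pairs: []
  density_anchor: O3
GM1:
  category: glycolipid
  head_atom: P
  scheme: midpoint_tail
  midpoint_atoms:
  - P
  - C2
  tail_atoms:
  - C14
  - C15
  - C16
  - C24
  - C25
  - C26
  anchor_atoms: []
  ch_pairs:
  - - C14
    - H14
  - - C15
    - H15
  - - C16
    - H16
  density_anchor: P
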