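# Dissociated transplanted tumors in which p53 restoration (doxycycline)
# triggers senescence of the GFP+ tumor cells. CD45 marks infiltrating
# immune cells; a viability dye channel gates live cells; singlet gating
# uses DAPI area/intensity as usual for dissociated tissue.
simulate:
  name: tumor_regression
  image_size_px: 64
  channels: [BF, DAPI, GFP, CD45, Zombie]
  population:
    cell_types:
      - type: tumor
        prev: 0.7
        positive_for: [GFP]
        area:
          sen: {mean_um2: 260, cv: 0.25}
          nonsen: {mean_um2: 200, cv: 0.25}
      - type: immune
        prev: 0.3
        positive_for: [CD45]
        area:
          sen: {mean_um2: 110, cv: 0.25}
          nonsen: {mean_um2: 85, cv: 0.25}
  samples:
    - sample_id: untreated
      n_cells: 2000
      p_stained: {tumor: 0.024, immune: 0.05}
      p_viable: 0.969
    - sample_id: dox
      n_cells: 2000
      p_stained: {tumor: 0.698, immune: 0.09}
      p_viable: 0.95
    - {sample_id: unstained, n_cells: 2000, unstained: true}
gates:
  - {name: singlets, type: singlet_dapi}
  - {name: focused, type: focus, parent: singlets}
  - {name: viable, type: control_threshold, feature: mean_px_Zombie,
     direction: below, quantile: 0.995, parent: focused}
  - {name: gfp_pos, type: control_threshold, feature: mean_px_GFP,
     direction: above, quantile: 0.99, parent: viable}
  - {name: gfp_neg, type: boolean, op: NOT, members: [gfp_pos], parent: viable}
  - {name: cd45_pos, type: control_threshold, feature: mean_px_CD45,
     direction: above, quantile: 0.99, parent: viable}
  - {name: immune, type: boolean, op: AND, members: [cd45_pos, gfp_neg],
     parent: viable}
  - {name: sa_pos, type: control_threshold, feature: bf_mean_pixel,
     direction: below, quantile: 0.001, parent: viable}
control_samples: [unstained]
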