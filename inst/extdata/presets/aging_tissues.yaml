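# SA-beta-gal positive cells in dissociated tissues of young (2-month) vs
# old (24-month) mice: subcutaneous adipose-derived stromal cells, spleen,
# small intestine, lymph node and lung. Low prevalences, so the
# SA-beta-gal gate uses a stricter control quantile (0.005) than the
# in-vitro default. Senescent cells are rendered larger than normal cells,
# supporting SA+ vs SA- area comparisons.
simulate:
  name: aging_tissues
  image_size_px: 64
  population:
    area:
      sen: {mean_um2: 160, cv: 0.3}
      nonsen: {mean_um2: 100, cv: 0.3}
  samples:
    - {sample_id: adipose_young, n_cells: 2000, p_stained: 0.014}
    - {sample_id: adipose_old, n_cells: 2000, p_stained: 0.138}
    - {sample_id: spleen_young, n_cells: 2000, p_stained: 0.0019}
    - {sample_id: spleen_old, n_cells: 2000, p_stained: 0.0353}
    - {sample_id: intestine_young, n_cells: 2000, p_stained: 0.003}
    - {sample_id: intestine_old, n_cells: 2000, p_stained: 0.033}
    - {sample_id: lymph_young, n_cells: 2000, p_stained: 0.0016}
    - {sample_id: lymph_old, n_cells: 2000, p_stained: 0.0148}
    - {sample_id: lung_young, n_cells: 2000, p_stained: 0.059}
    - {sample_id: lung_old, n_cells: 2000, p_stained: 0.067}
    - {sample_id: unstained, n_cells: 2000, unstained: true}
  channels: [BF, DAPI]
gates:
  - {name: singlets, type: singlet_dapi}
  - {name: focused, type: focus, parent: singlets}
  - {name: sa_pos, type: control_threshold, feature: bf_mean_pixel,
     direction: below, quantile: 0.001, parent: focused}
  - {name: sa_neg, type: boolean, op: NOT, members: [sa_pos], parent: focused}
control_samples: [unstained]
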