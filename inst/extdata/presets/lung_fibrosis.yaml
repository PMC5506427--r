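# Dissociated lungs after bleomycin-induced pulmonary fibrosis vs control.
# pCK marks epithelial cells, CD45 immune cells; SA-beta-gal percentages
# are reported per cell-type compartment. Ki67 positivity and BrdU
# incorporation are specified conditionally on staining, so the overlap of
# SA-beta-gal with the proliferation markers is injected ground truth.
simulate:
  name: lung_fibrosis
  image_size_px: 64
  channels: [BF, DAPI, CD45, pCK, Ki67, BrdU]
  population:
    p_marker_pos:
      Ki67: {stained: 0.0088, unstained: 0.764}
      BrdU: {stained: 0.02, unstained: 0.764}
    cell_types:
      - type: epithelial
        prev: 0.25
        positive_for: [pCK]
        area:
          sen: {mean_um2: 240, cv: 0.25}
          nonsen: {mean_um2: 180, cv: 0.25}
      - type: immune
        prev: 0.55
        positive_for: [CD45]
        area:
          sen: {mean_um2: 110, cv: 0.25}
          nonsen: {mean_um2: 85, cv: 0.25}
      - type: other
        prev: 0.2
        positive_for: []
        area:
          sen: {mean_um2: 200, cv: 0.25}
          nonsen: {mean_um2: 150, cv: 0.25}
  samples:
    - sample_id: control_lung
      n_cells: 2000
      p_stained: {epithelial: 0.0114, immune: 0.1611, other: 0.02}
    - sample_id: bleomycin_lung
      n_cells: 2000
      p_stained: {epithelial: 0.0896, immune: 0.153, other: 0.05}
    - {sample_id: unstained, n_cells: 2000, unstained: true}
gates:
  - {name: singlets, type: singlet_dapi}
  - {name: focused, type: focus, parent: singlets}
  - {name: sa_pos, type: control_threshold, feature: bf_mean_pixel,
     direction: below, quantile: 0.001, parent: focused}
  - {name: sa_neg, type: boolean, op: NOT, members: [sa_pos], parent: focused}
  - {name: pck_pos, type: control_threshold, feature: mean_px_pCK,
     direction: above, quantile: 0.99, parent: focused}
  - {name: cd45_pos, type: control_threshold, feature: mean_px_CD45,
     direction: above, quantile: 0.99, parent: focused}
  - {name: ki67_pos, type: control_threshold, feature: max_px_Ki67,
     direction: above, quantile: 0.99, parent: focused}
  - {name: ki67_neg, type: boolean, op: NOT, members: [ki67_pos], parent: focused}
  - {name: brdu_pos, type: control_threshold, feature: mean_px_BrdU,
     direction: above, quantile: 0.99, parent: focused}
  - {name: brdu_neg, type: boolean, op: NOT, members: [brdu_pos], parent: focused}
  - {name: prolif_neg, type: boolean, op: AND, members: [ki67_neg, brdu_neg],
     parent: focused}
control_samples: [unstained]
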