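# Time course after a 48 h etoposide pulse in human fibroblasts: growing
# (day 0), day 2 (acute DNA damage) and day 8 (established DIS). Combines
# SA-beta-gal darkness with gamma-H2AX focus counting and nuclear HMGB1 /
# Ki67 positivity; the combined senescence gate is SA+ AND HMGB1-.
# Focus-positivity and HMGB1 probabilities in the DIS sample are specified
# conditionally on staining so marker-overlap statistics are injected.
simulate:
  name: dis_timecourse
  channels: [BF, DAPI, gH2AX, HMGB1, Ki67]
  population:
    area:
      sen: {mean_um2: 668.9, cv: 0.22}
      nonsen: {mean_um2: 461, cv: 0.22}
  samples:
    - sample_id: growing
      n_cells: 2000
      senescent_prev: 0
      p_stained_nonsen: 0.041
      p_focus_pos: 0.078
      p_marker_pos:
        HMGB1: {stained: 0.0537, unstained: 0.857}
        Ki67: 0.57
    - sample_id: day2
      n_cells: 2000
      p_stained: 0.2625
      p_focus_pos: 0.52
      p_marker_pos:
        HMGB1: 0.348
        Ki67: 0.35
    - sample_id: dis
      n_cells: 2000
      senescent_prev: 1
      p_stained_sen: 0.8824
      p_focus_pos: {stained: 0.2928, unstained: 0.209}
      p_marker_pos:
        HMGB1: {stained: 0.0164, unstained: 0.3448}
        Ki67: 0.08
    - {sample_id: unstained, n_cells: 2000, unstained: true}
gates:
  - {name: singlets, type: singlet_bf}
  - {name: focused, type: focus, parent: singlets}
  - {name: sa_pos, type: control_threshold, feature: bf_mean_pixel,
     direction: below, quantile: 0.01, parent: focused}
  - {name: sa_neg, type: boolean, op: NOT, members: [sa_pos], parent: focused}
  - {name: gh2ax_pos, type: threshold, feature: spot_count,
     direction: above, cutoff: 2.5, parent: focused}
  - {name: hmgb1_pos, type: control_threshold, feature: mean_px_HMGB1,
     direction: above, quantile: 0.99, parent: focused}
  - {name: hmgb1_neg, type: boolean, op: NOT, members: [hmgb1_pos], parent: focused}
  - {name: ki67_pos, type: control_threshold, feature: max_px_Ki67,
     direction: above, quantile: 0.99, parent: focused}
  - {name: sen_combined, type: boolean, op: AND, members: [sa_pos, hmgb1_neg],
     parent: focused}
control_samples: [unstained]
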