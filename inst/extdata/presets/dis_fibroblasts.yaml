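# Etoposide-induced senescent (DIS) vs growing human fibroblasts,
# SA-beta-gal scored on the bright-field channel against an unstained
# reference sample; cell-area report for the same populations.
simulate:
  name: dis_fibroblasts
  channels: [BF]
  population:
    area:
      sen: {mean_um2: 668.9, cv: 0.22}
      nonsen: {mean_um2: 461, cv: 0.22}
  samples:
    - {sample_id: growing, n_cells: 2000, senescent_prev: 0, p_stained_nonsen: 0.048}
    - {sample_id: dis, n_cells: 2000, senescent_prev: 1, p_stained_sen: 0.896}
    - {sample_id: unstained, n_cells: 2000, unstained: true}
gates:
  - {name: singlets, type: singlet_bf}
  - {name: focused, type: focus, parent: singlets}
  - {name: sa_pos, type: control_threshold, feature: bf_mean_pixel,
     direction: below, quantile: 0.01, parent: focused}
  - {name: sa_neg, type: boolean, op: NOT, members: [sa_pos], parent: focused}
control_samples: [unstained]
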