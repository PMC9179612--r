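# Feature schema: names, order and units of the 23 window features.
# vstd_* : root-mean-square of a sub-window series            [G]
# vmax_* : maximum absolute value of a sub-window series      [G]
# vebda  : mean Euclidean norm of sub-window mean acceleration [G]
# obda   : mean L1 deviation of sub-window mean acceleration   [G]
# rho_*  : Pearson correlation of normalized axis-mean series  [-]
version: 1
features:
  - {name: vstd_ave_x, unit: G}
  - {name: vmax_ave_x, unit: G}
  - {name: vstd_ave_y, unit: G}
  - {name: vmax_ave_y, unit: G}
  - {name: vstd_ave_z, unit: G}
  - {name: vmax_ave_z, unit: G}
  - {name: vstd_abs_x, unit: G}
  - {name: vmax_abs_x, unit: G}
  - {name: vstd_abs_y, unit: G}
  - {name: vmax_abs_y, unit: G}
  - {name: vstd_abs_z, unit: G}
  - {name: vmax_abs_z, unit: G}
  - {name: vstd_std_x, unit: G}
  - {name: vmax_std_x, unit: G}
  - {name: vstd_std_y, unit: G}
  - {name: vmax_std_y, unit: G}
  - {name: vstd_std_z, unit: G}
  - {name: vmax_std_z, unit: G}
  - {name: vebda, unit: G}
  - {name: obda, unit: G}
  - {name: rho_xy, unit: "-"}
  - {name: rho_xz, unit: "-"}
  - {name: rho_yz, unit: "-"}
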