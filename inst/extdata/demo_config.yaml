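# Demo screening configuration: one interacting pair and one
# non-interacting pair, two cells each, short acquisitions.
# Run with:  run_pipeline(system.file("extdata/demo_config.yaml",
#                                     package = "fccstools"))
seed: 42
optics:
  w_xy_g: 0.2
  w_xy_r: 0.2
  kappa_g: 5
  kappa_r: 5
  crosstalk_g_to_r: 0.05
calibration:
  D_g: 435      # green-channel dye, um^2/s
  D_r: 341      # red-channel dye
  D_x: 420      # dual-channel dye (cross-correlation volume)
  duration: 5
  n_repeats: 1
simulation:
  duration: 5          # s per cell (screens use 20-60 s)
  n_cells: 2
  background_fraction: 0.1
fit:
  kind: anomalous
thresholds:
  kd_detect: 1.0e-6    # reliable FCCS detection bound, mol/L
manifest:
  - strain: pairAB
    protein_g: A_green
    protein_r: B_red
    total_g: 3.0e-7    # mol/L
    total_r: 3.0e-7
    K_D: 3.0e-7        # true dissociation constant, mol/L
    D_g: 3             # um^2/s
    D_r: 3
  - strain: controlCD
    protein_g: C_green
    protein_r: D_red
    total_g: 2.0e-7
    total_r: 2.0e-7
    D_g: 3
    D_r: 3
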