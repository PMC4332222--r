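# Versioned grade presets for the synthetic cohort generator.
#
# Mechanics: lung-level constant-phase parameters at full recruitment.
#   h_lung  - tissue elastance H of the whole (fully recruited) lung,
#             cmH2O/mL; per-compartment H = h_lung * n_compartments.
#   eta     - hysteresivity G/H (dimensionless); per-compartment eta is drawn
#             with coefficient of variation eta_cv, which disperses the
#             constant-phase exponent alpha across compartments and is the
#             main source of frequency-dependent heterogeneity (E_het).
#   raw_comp- per-compartment peripheral airway resistance, cmH2O.s/mL.
#   cv      - coefficient of variation of per-compartment H and Raw draws.
#   pc      - closing-pressure distribution (cmH2O), truncated normal;
#             a compartment is open iff PEEP >= Pc.
#   tf      - per-animal tissue-fraction target distribution (fraction).
# Calibration: analytic first pass from the closed-form parallel
# constant-phase impedance, refined by a coarse grid search against cohort
# medians of the printed group values; frozen at version 1.
version: 1
beta_tf_coupling: 3.5
n_compartments: 12
Rc: 0.02
Ic: 0.0003
grades:
  A0_native:
    h_lung: 3.5
    eta: 0.15
    eta_cv: 0.05
    raw_comp: 0.10
    cv: 0.10
    pc: {mean: -3.0, sd: 1.0, lower: -6.0, upper: -0.5}
    ensure_open: false
    tf: {mean: 0.225, sd: 0.015}
  A0_iso:
    h_lung: 3.8
    eta: 0.15
    eta_cv: 0.05
    raw_comp: 0.10
    cv: 0.10
    pc: {mean: -3.0, sd: 1.0, lower: -6.0, upper: -0.5}
    ensure_open: false
    tf: {mean: 0.225, sd: 0.015}
  A1:
    h_lung: 6.0
    eta: 0.35
    eta_cv: 0.25
    raw_comp: 0.4
    cv: 0.25
    pc: {mean: 0.4, sd: 1.35, lower: -4.0, upper: 7.0}
    ensure_open: true
    tf: {mean: 0.261, sd: 0.042}
  A2:
    h_lung: 20.0
    eta: 0.25
    eta_cv: 0.35
    raw_comp: 1.2
    cv: 0.50
    pc: {mean: 0.6, sd: 2.6, lower: -4.0, upper: 12.0}
    ensure_open: true
    tf: {mean: 0.338, sd: 0.051}
  A3:
    h_lung: 20.5
    eta: 0.25
    eta_cv: 0.40
    raw_comp: 0.55
    cv: 0.70
    pc: {mean: 10.0, sd: 3.0, lower: -2.0, upper: 20.0}
    ensure_open: true
    tf: {mean: 0.621, sd: 0.047}
histology:
  size_px: 1024
  pixel_size_um: 0.5
  n_wall_points: 260
  vessel_ring_px: 3
  blur_sigma: 1.0
  noise_sd: 8.0
  gray_tissue: 40
  gray_air: 220
  grades:
    A0_native:  {n_vessels: 4,  n_infiltrates: 0,  annulus_px: 0,  wall_px: 6}
    A0_iso:     {n_vessels: 4,  n_infiltrates: 0,  annulus_px: 0,  wall_px: 6}
    A1:         {n_vessels: 6,  n_infiltrates: 3,  annulus_px: 6,  wall_px: 6}
    A2:         {n_vessels: 10, n_infiltrates: 7,  annulus_px: 12, wall_px: 6}
    A3:         {n_vessels: 12, n_infiltrates: 10, annulus_px: 25, wall_px: 12}
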