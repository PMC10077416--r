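# Default synthetic mediastinal study configuration.
# All lengths in mm, doses in Gy, LET in keV/um.
seed: 1

grid:
  shape: [150, 100, 50]     # x (lateral), y (anterior->posterior), z (sup-inf)
  spacing: [2, 2, 2]        # isotropic 2 mm

phantom:
  body:
    semi_axes: [145, 95]    # axial ellipse; body extends the full z range
  ctv:
    centre: [0, -30, 0]     # anterior mediastinum
    semi_axes: [25, 20, 25]
  structures:
    heart:
      shape: ellipsoid
      centre: [15, 10, -5]  # posterior-inferior to the CTV
      semi_axes: [35, 32, 35]
    left_atrium:            # abuts the CTV's posterior-distal surface
      shape: ellipsoid
      centre: [18, -2, 0]
      semi_axes: [12, 10, 12]
    lung_left:
      shape: ellipsoid
      centre: [-85, 5, 0]
      semi_axes: [40, 55, 45]
    lung_right:
      shape: ellipsoid
      centre: [85, 5, 0]
      semi_axes: [40, 55, 45]
    spinal_cord:
      shape: zcylinder
      centre: [0, 70, 0]
      radius: 5
      half_length: 120
    esophagus:
      shape: zcylinder
      centre: [5, 25, 0]
      radius: 5
      half_length: 120
    lmca:                   # deliberately below 0.1 cc ("structure too small")
      shape: zcylinder
      centre: [25, 5, 5]
      radius: 2.5
      half_length: 1

beam:
  aperture_margin_mm: 10
  penumbra_sigma_mm: 4
  layer_spacing_mm: 3

depth_curve:
  plateau_dose: 0.35
  peak_width_mm: 5
  straggling_sigma_mm: 2.5
  let_plateau: 1.5
  let_scale: 25
  let_softening_mm: 2
  let_cap: 15

plans:                      # gantry angles in degrees, 0 = anterior
  1F: [0]
  2F: [10, 350]
  2F-wide: [30, 330]
  3F: [10, 350, 180]

prescription:
  total_dose: 19.8
  n_fractions: 11

rbe:
  fixed: 1.1
  alpha_beta: [2, 3, 10]
  # McNamara coefficients may be overridden here:
  # coefficients: {c1: 0.99064, c2: 0.35605, c3: 1.1012, c4: 0.0038703}

metrics:
  dvh_bins: 200
  vx_thresholds: [5, 10]
  hot_volume_cc: 0.1
  threshold_fraction: 0.05  # LET defined only above this fraction of max dose
  let_threshold: 6          # keV/um, "high LET"
  overlap_dose_fraction: 0.8
  delta_threshold: 3        # Gy(RBE)

noise:
  dose_sd_frac: 0.0         # deterministic by default
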