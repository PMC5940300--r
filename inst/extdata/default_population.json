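{
  "comment": "Default crypt-population calibration: geometry, channel anchors and per-zone cell-cycle composition of the cycling (UEA-negative) lineage. Intensities are arbitrary units anchored so that a transit-amplifying cell entering S phase has DNA-bound Mcm2 = 1.0.",
  "crypt_length_um": 140,
  "crypt_radius_um": 15,
  "stem_zone_max_um": 40,
  "differentiated_zone_min_um": 120,
  "noise_cv": 0.15,
  "dna_noise_cv": 0.05,
  "stem_license_factor": 2.0,
  "background_level": 0.05,
  "stem_zone_classes": { "stem": 0.75, "paneth": 0.22, "LRC": 0.03 },
  "channel_anchors": {
    "total_high": 1.0,
    "total_negative": 0.02,
    "ki67_g0": 0.05,
    "ki67_transition": 0.3,
    "ki67_g1": 1.0,
    "ki67_s": 1.1,
    "ki67_g2m": 1.2,
    "edu_positive": 1.0,
    "edu_negative": 0.02,
    "lgr5_stem": 1.0,
    "lgr5_lrc": 0.5,
    "lgr5_other": 0.02,
    "licensed_min_progress": 0.3,
    "s_late_boundary": 0.6,
    "h2b_initial": 1.0
  },
  "division_lambda": { "stem": 2, "TA": 5, "differentiated": 5 },
  "zones": [
    { "start": 0,   "end": 20,  "G0": 0.02, "TRANSITION": 0.07, "UNLICENSED_G1": 0.58, "LICENSED_G1": 0.10, "S_EARLY_MID": 0.11, "LATE_S_G2": 0.06, "G2M": 0.06 },
    { "start": 20,  "end": 40,  "G0": 0.02, "TRANSITION": 0.07, "UNLICENSED_G1": 0.58, "LICENSED_G1": 0.10, "S_EARLY_MID": 0.11, "LATE_S_G2": 0.06, "G2M": 0.06 },
    { "start": 40,  "end": 60,  "G0": 0.04, "TRANSITION": 0.06, "UNLICENSED_G1": 0.14, "LICENSED_G1": 0.26, "S_EARLY_MID": 0.24, "LATE_S_G2": 0.16, "G2M": 0.10 },
    { "start": 60,  "end": 80,  "G0": 0.04, "TRANSITION": 0.05, "UNLICENSED_G1": 0.13, "LICENSED_G1": 0.18, "S_EARLY_MID": 0.28, "LATE_S_G2": 0.20, "G2M": 0.12 },
    { "start": 80,  "end": 100, "G0": 0.05, "TRANSITION": 0.07, "UNLICENSED_G1": 0.16, "LICENSED_G1": 0.12, "S_EARLY_MID": 0.26, "LATE_S_G2": 0.22, "G2M": 0.12 },
    { "start": 100, "end": 120, "G0": 0.10, "TRANSITION": 0.14, "UNLICENSED_G1": 0.36, "LICENSED_G1": 0.00, "S_EARLY_MID": 0.00, "LATE_S_G2": 0.30, "G2M": 0.10 },
    { "start": 120, "end": 140, "G0": 0.45, "TRANSITION": 0.28, "UNLICENSED_G1": 0.22, "LICENSED_G1": 0.00, "S_EARLY_MID": 0.00, "LATE_S_G2": 0.00, "G2M": 0.05 }
  ]
}
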