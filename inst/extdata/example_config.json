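{
  "seed": 1,
  "geometry": {
    "heart_semi_axes": [30, 30, 35],
    "heart_center": [0, 0, 0],
    "heart_edge_mm": 4,
    "tank_scale": [3.5, 3.5, 2.5],
    "tank_edge_mm": 14,
    "n_sock": 108,
    "n_tank": 256,
    "n_tank_recording": 128
  },
  "camera": {
    "X_COP": [0, 0, 300],
    "X_FOC": [0, 0, 0],
    "roll": 0,
    "init_cop_offset_mm": 20,
    "init_foc_offset_mm": 5,
    "init_roll_offset": 0.02,
    "init_scale_factor": 1.03,
    "ref_jitter_px": 1
  },
  "protocol": {
    "n_beats": 2,
    "cycle_ms": 500,
    "elec_rate": 2000,
    "optical_rate": 1000,
    "stim_delay_ms": 50,
    "optical_t0_ms": 40,
    "elec_snr_db": 30
  },
  "sequences": [
    {
      "name": "seq_01",
      "pacing": "anterior",
      "cv_base": 1,
      "apd_base": 190,
      "perfusion": null,
      "noise_snr_db": 20
    },
    {
      "name": "seq_02",
      "pacing": "anterior",
      "cv_base": 1,
      "apd_base": 190,
      "perfusion": {
        "center": "anterior_offset",
        "radius_mm": 20,
        "cv_factor": 0.7,
        "apd_delta": 40
      },
      "noise_snr_db": 20
    }
  ],
  "mfs": {
    "deflate": 0.8,
    "inflate": 1.2,
    "forward_factors": [0.7, 1.3],
    "lam_mode": "median",
    "gaf_radius_mm": 20
  },
  "markers": {
    "rt_window": [50, 450],
    "ecgi_rt_window": [100, 420]
  },
  "metrics": {
    "cutoff_px": 5
  }
}
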