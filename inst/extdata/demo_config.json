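{
  "seed": 20210915,
  "imaging": {
    "synthetic": true,
    "n_patients": 15,
    "grid_shape": [32, 32, 32],
    "voxel_spacing_mm": [2, 2, 2],
    "background_uptake": 1.0,
    "noise_sd": 0.05,
    "levels_pct": [40, 50, 60, 70],
    "target_level_pct": 40,
    "n_resamples": 100,
    "injection": {
      "injected_activity_MBq": 180,
      "body_weight_kg": 72,
      "injection_time": "2021-01-01T09:00:00",
      "acquisition_time": "2021-01-01T09:12:00"
    }
  },
  "survival": {
    "synthetic": true,
    "n": 120,
    "cutoff": 3.0,
    "effect_log_scale": 0.8,
    "shape": 2,
    "scale_base": 12,
    "censor_rate": 0.2,
    "suv_range": [1, 8],
    "min_group": 5,
    "model": "loglogistic_aft"
  },
  "wbt": {
    "synthetic": true,
    "n_genes": 500,
    "n_samples": 27,
    "n_planted": 10,
    "beta": 1.0,
    "grade_confounding": 0.5,
    "n_timepoints_per_patient": 3,
    "mad_top_fraction": 0.10,
    "n_checkpoint_genes": 5
  }
}
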