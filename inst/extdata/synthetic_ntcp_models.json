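[
  {
    "endpoint": "dysphagia_g2",
    "intercept": -3.1,
    "dose_betas": {
      "oral_cavity": 0.012,
      "pcm_superior": 0.01,
      "pcm_medius": 0.007,
      "pcm_inferior": 0.005
    },
    "baseline_covariate": "baseline_dysphagia",
    "baseline_betas": {
      "none": 0,
      "minor": 0.4,
      "moderate_severe": 0.9
    }
  },
  {
    "endpoint": "xerostomia_g2",
    "intercept": -2.7,
    "dose_betas": {
      "parotid_left": 0.016,
      "parotid_right": 0.016,
      "submandibular_left": 0.005,
      "submandibular_right": 0.005,
      "oral_cavity": 0.004
    },
    "baseline_covariate": "baseline_xerostomia",
    "baseline_betas": {
      "none": 0,
      "minor": 0.4,
      "moderate_severe": 0.9
    }
  },
  {
    "endpoint": "dysphagia_g3",
    "intercept": -5.2,
    "dose_betas": {
      "oral_cavity": 0.01,
      "pcm_superior": 0.009,
      "pcm_medius": 0.006,
      "pcm_inferior": 0.004
    },
    "baseline_covariate": "baseline_dysphagia",
    "baseline_betas": {
      "none": 0,
      "minor": 0.5,
      "moderate_severe": 1
    }
  },
  {
    "endpoint": "xerostomia_g3",
    "intercept": -5,
    "dose_betas": {
      "parotid_left": 0.013,
      "parotid_right": 0.013,
      "submandibular_left": 0.004,
      "submandibular_right": 0.004,
      "oral_cavity": 0.003
    },
    "baseline_covariate": "baseline_xerostomia",
    "baseline_betas": {
      "none": 0,
      "minor": 0.5,
      "moderate_severe": 1
    }
  }
]
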