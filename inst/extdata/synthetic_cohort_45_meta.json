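{
  "seed": 20260101,
  "n": 45,
  "generator": {
    "n": 45,
    "pb_median": 40,
    "pb_log_sd": 0.8,
    "covariate_probs": {
      "sex": [0.422222222222222, 0.577777777777778],
      "mobilization": [0.733333333333333, 0.266666666666667],
      "tumor_type": [0.466666666666667, 0.244444444444444, 0.0666666666666667, 0.222222222222222],
      "arm": [0.666666666666667, 0.333333333333333]
    },
    "age_by_tumor": {
      "neuroblastoma": [3.7, 2.1],
      "other": [8.9, 4.8]
    },
    "age_range": [1, 18],
    "truth": {
      "coefficients": {
        "(Intercept)": 0.01,
        "pb_cd34": 0.13,
        "tumor_binaryneuroblastoma": 3
      },
      "sigma": 0.54,
      "kappa": 0,
      "error": "combined",
      "covariates": "tumor_binary"
    }
  }
}
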