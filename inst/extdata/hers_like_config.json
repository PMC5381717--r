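{
  "partition_boundaries": [0, 91, 273, 455, 637, 819, 1001, 1183, 1365, 1547, 1729, 1911, 2093],
  "scale": 2093,
  "long_covariates": [],
  "surv_terms": ["1", "rstart", "rstart^2", "age", "V2", "V3", "V4"],
  "transforms": {
    "age": [35, 7]
  },
  "association": "intercept_slope",
  "gamma_tv": false,
  "lambda_grid": [0.001, 0.00215443469003188, 0.00464158883361278, 0.01, 0.0215443469003188, 0.0464158883361278, 0.1, 0.215443469003188, 0.464158883361278, 1, 2.15443469003188, 4.64158883361278, 9.99999999999999, 21.5443469003188, 46.4158883361278, 100],
  "seed": 1
}
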