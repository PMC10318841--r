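{
  "name": "five_item_default",
  "version": "1.0",
  "items": {
    "id": [
      "sample_representativeness",
      "cv_scheme",
      "external_validation",
      "reporting_transparency",
      "availability"
    ],
    "name": [
      "Sample representativeness (size and sites)",
      "Cross-validation scheme",
      "External (independent-sample) validation",
      "Reporting transparency (performance metrics)",
      "Data/model availability"
    ],
    "max": [2, 2, 2, 2, 2]
  },
  "params": {
    "n_threshold": 200,
    "multi_site_min": 2,
    "cv_points": {
      "none": 0,
      "other": 0,
      "LOOCV": 1,
      "kfold": 2,
      "nested_kfold": 2
    },
    "external_points": {
      "none": 0,
      "within_country": 1,
      "cross_country": 2
    },
    "per_metric_points": 0.5,
    "transparency_cap": 2
  }
}
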