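{
  "version": "1.0",
  "provenance": "EAR test, Italian adult normative sample (N = 522), norms version 1.0 (2024)",
  "age_range": [17, 88],
  "education_range": [5, 24],
  "caution_age": 65,
  "er": {
    "adjustment": {
      "beta_age2": 0.002,
      "centering_c": 1811.257,
      "sex_offset": 0.818
    },
    "thresholds": {
      "t0": 42.35,
      "t1": 46.09,
      "t2": 48.87,
      "t3": 51.45
    }
  },
  "ea": {
    "adjustment": {
      "beta_age2": 0.002,
      "centering_c": 1811.257,
      "sex_offset": 0.42
    },
    "thresholds": {
      "t0": 41.25,
      "t1": 45.09,
      "t2": 47.77,
      "t3": 50.62
    }
  },
  "checksum": 3997246
}
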