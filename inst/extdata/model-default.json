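{
  "kind": "linear_svm_ovr",
  "version": "1",
  "seed": 42,
  "feature_names": ["sd1_ms", "sd2_ms", "sd_ratio", "dnorm_sd", "dnorm_p95", "extreme_window_ratio", "pac_rate", "apen"],
  "classes": ["AF", "NO_RISK", "PAF_RISK"],
  "center": {
    "sd1_ms": 57.1555181162317,
    "sd2_ms": 103.791994499564,
    "sd_ratio": 0.535226065050984,
    "dnorm_sd": 0.059116746874665,
    "dnorm_p95": 0.122626430268812,
    "extreme_window_ratio": 0.966670007601342,
    "pac_rate": 85.7511518715015,
    "apen": 1.74457373880733
  },
  "scale": {
    "sd1_ms": 40.6195923905205,
    "sd2_ms": 64.4184183068707,
    "sd_ratio": 0.0997067338638865,
    "dnorm_sd": 0.0498134062157182,
    "dnorm_p95": 0.109292437170442,
    "extreme_window_ratio": 0.0474979026110447,
    "pac_rate": 112.815611941535,
    "apen": 0.228745215395325
  },
  "weights": {
    "AF": {
      "sd1_ms": 0.199753757564093,
      "sd2_ms": 0.393981424710534,
      "sd_ratio": -0.138546994149553,
      "dnorm_sd": 0.34703609124455,
      "dnorm_p95": 0.377152982219564,
      "extreme_window_ratio": -0.257825600629626,
      "pac_rate": 0.472382121538033,
      "apen": -0.211587237142764
    },
    "NO_RISK": {
      "sd1_ms": -0.627773004137972,
      "sd2_ms": -0.727047934848818,
      "sd_ratio": -0.488427102190509,
      "dnorm_sd": -0.529338637145903,
      "dnorm_p95": -0.534714935564925,
      "extreme_window_ratio": -0.259423324244568,
      "pac_rate": -6.30237492564451,
      "apen": 0.631771405983767
    },
    "PAF_RISK": {
      "sd1_ms": 1.44350132078402,
      "sd2_ms": 1.23891896779391,
      "sd_ratio": 0.225258555389056,
      "dnorm_sd": -2.15578571756599,
      "dnorm_p95": -3.00215337547687,
      "extreme_window_ratio": 2.31643778554448,
      "pac_rate": 1.71298918839829,
      "apen": 0.0169379585493246
    }
  },
  "intercept": {
    "AF": -0.36798137954057,
    "NO_RISK": -5.96327048234707,
    "PAF_RISK": -1.18630027740885
  }
}
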