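{
  "description": "Published logistic regression of TURBT complexity on the five predictor domains (131 conclusive expert-rated scenarios). Only marginal standard errors were published; the covariance matrix shipped with this fixture is the diagonal approximation diag(se^2).",
  "provenance": "published",
  "n_obs": 131,
  "intercept": -13.34,
  "intercept_se": 2.31,
  "coefficients": {
    "history": 0.99,
    "number": 0.96,
    "location": 1.44,
    "size": 1.04,
    "access": 1.10
  },
  "std_errors": {
    "history": 0.32,
    "number": 0.23,
    "location": 0.33,
    "size": 0.26,
    "access": 0.26
  }
}
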