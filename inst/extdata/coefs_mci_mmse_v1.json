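{
  "group": "MCI",
  "outcome": "mmse",
  "bounds": [0, 30],
  "time_center": 2.3,
  "description": "Reference backward-selected biomarker model for MMSE decline in amyloid-positive MCI (pooled over 25 imputed data sets; time centered by subtracting 2.3 years; interactions use centered time).",
  "terms": [
    {"term": "(Intercept)",     "covariate": null,    "transform": "identity", "role": "intercept",   "estimate": 12.9446, "se": 2.4238},
    {"term": "time_c",          "covariate": null,    "transform": "identity", "role": "time",        "estimate": -1.6700, "se": 1.1730},
    {"term": "time_c2",         "covariate": null,    "transform": "identity", "role": "time",        "estimate": -0.2090, "se": 0.0486},
    {"term": "time_c3",         "covariate": null,    "transform": "identity", "role": "time",        "estimate": 0.0141,  "se": 0.0091},
    {"term": "age",             "covariate": "age",   "transform": "identity", "role": "main",        "estimate": 0.0147,  "se": 0.0239},
    {"term": "sex_male",        "covariate": "sex",   "transform": "identity", "role": "main",        "estimate": 0.4329,  "se": 0.3227},
    {"term": "mmse_bl",         "covariate": "mmse_bl", "transform": "identity", "role": "main",      "estimate": 0.5283,  "se": 0.0534},
    {"term": "log_ptau",        "covariate": "ptau",  "transform": "log",      "role": "main",        "estimate": -1.1162, "se": 0.4153},
    {"term": "abeta",           "covariate": "abeta", "transform": "identity", "role": "main",        "estimate": 0.0008,  "se": 0.0008},
    {"term": "age:time_c",      "covariate": "age",   "transform": "identity", "role": "interaction", "estimate": 0.0188,  "se": 0.0142},
    {"term": "abeta:time_c",    "covariate": "abeta", "transform": "identity", "role": "interaction", "estimate": 0.0006,  "se": 0.0005},
    {"term": "sex_male:time_c", "covariate": "sex",   "transform": "identity", "role": "interaction", "estimate": 0.2884,  "se": 0.1926},
    {"term": "log_ptau:time_c", "covariate": "ptau",  "transform": "log",      "role": "interaction", "estimate": -0.3894, "se": 0.2484}
  ]
}
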