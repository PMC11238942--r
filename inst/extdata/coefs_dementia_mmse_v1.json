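{
  "group": "dementia",
  "outcome": "mmse",
  "bounds": [0, 30],
  "time_center": 2.3,
  "description": "Reference backward-selected biomarker model for MMSE decline in amyloid-positive mild dementia (pooled over 25 imputed data sets; time centered by subtracting 2.3 years; interactions use centered time).",
  "terms": [
    {"term": "(Intercept)",    "covariate": null,      "transform": "identity", "role": "intercept",   "estimate": -10.2450, "se": 2.4825},
    {"term": "time_c",         "covariate": null,      "transform": "identity", "role": "time",        "estimate": -9.9597,  "se": 1.4078},
    {"term": "time_c2",        "covariate": null,      "transform": "identity", "role": "time",        "estimate": -0.2196,  "se": 0.0582},
    {"term": "time_c3",        "covariate": null,      "transform": "identity", "role": "time",        "estimate": 0.0227,   "se": 0.0139},
    {"term": "age",            "covariate": "age",     "transform": "identity", "role": "main",        "estimate": 0.1020,   "se": 0.0274},
    {"term": "sex_male",       "covariate": "sex",     "transform": "identity", "role": "main",        "estimate": -0.0811,  "se": 0.2718},
    {"term": "mmse_bl",        "covariate": "mmse_bl", "transform": "identity", "role": "main",        "estimate": 1.0006,   "se": 0.0561},
    {"term": "apoe4",          "covariate": "apoe4",   "transform": "identity", "role": "main",        "estimate": 0.5419,   "se": 0.2842},
    {"term": "log_ptau",       "covariate": "ptau",    "transform": "log",      "role": "main",        "estimate": -1.0403,  "se": 0.2990},
    {"term": "abeta",          "covariate": "abeta",   "transform": "identity", "role": "main",        "estimate": 0.0019,   "se": 0.0010},
    {"term": "age:time_c",     "covariate": "age",     "transform": "identity", "role": "interaction", "estimate": 0.0376,   "se": 0.0156},
    {"term": "mmse_bl:time_c", "covariate": "mmse_bl", "transform": "identity", "role": "interaction", "estimate": 0.1299,   "se": 0.0345},
    {"term": "apoe4:time_c",   "covariate": "apoe4",   "transform": "identity", "role": "interaction", "estimate": 0.4768,   "se": 0.1636},
    {"term": "abeta:time_c",   "covariate": "abeta",   "transform": "identity", "role": "interaction", "estimate": 0.0009,   "se": 0.0006}
  ]
}
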