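{
  "version": "1.0",
  "note": "Calibration for the synthetic COPD cohort generator. Biomarker marginals are median/q1/q3 in as-printed units (pg/mL; MMP-9 magnitudes as printed). dlco_pct stage profiles are SYNTHETIC stand-ins (no published stage-stratified DLCO summary exists in the source tables); they follow the usual decline of percent-predicted diffusing capacity with GOLD stage.",
  "biomarkers": ["il6", "il8", "il16", "mcp1", "mmp9", "parc", "tnfa", "vegf"],
  "lod": {
    "il6": 0.70, "il8": 3.50, "il16": 6.20, "tnfa": 1.60,
    "mcp1": 5.0, "parc": 10.0, "vegf": 5.0, "mmp9": 156.0
  },
  "lod_note": "ELISA lower limits of detection, pg/mL. MMP-9 printed as 0.156 ng/mL, carried here on the pg/mL scale of its marginals.",
  "spearman_target": [
    [1.00, 0.53, 0.06, 0.11, -0.06, 0.09, 0.34, 0.09],
    [0.53, 1.00, 0.16, 0.14, 0.04, 0.10, 0.35, 0.08],
    [0.06, 0.16, 1.00, 0.05, -0.18, -0.08, 0.52, -0.35],
    [0.11, 0.14, 0.05, 1.00, 0.05, 0.24, 0.12, 0.14],
    [-0.06, 0.04, -0.18, 0.05, 1.00, 0.11, -0.22, 0.51],
    [0.09, 0.10, -0.08, 0.24, 0.11, 1.00, -0.07, 0.19],
    [0.34, 0.35, 0.52, 0.12, -0.22, -0.07, 1.00, -0.22],
    [0.09, 0.08, -0.35, 0.14, 0.51, 0.19, -0.22, 1.00]
  ],
  "overall": {
    "n": 253,
    "markers": {
      "il6":  {"median": 6.4,   "q1": 2.8,   "q3": 14.4},
      "il8":  {"median": 9.9,   "q1": 6.5,   "q3": 16.3},
      "il16": {"median": 331,   "q1": 239,   "q3": 547},
      "tnfa": {"median": 18.1,  "q1": 8.5,   "q3": 67.8},
      "mmp9": {"median": 5767,  "q1": 3057,  "q3": 20700},
      "vegf": {"median": 71.1,  "q1": 31.7,  "q3": 165.4},
      "parc": {"median": 52372, "q1": 34358, "q3": 66350},
      "mcp1": {"median": 527,   "q1": 410,   "q3": 711}
    }
  },
  "stages": [
    {
      "stage": 1,
      "n": 18,
      "clinical": {
        "age":      {"mean": 59,   "sd": 13},
        "bmi":      {"mean": 26,   "sd": 6},
        "fev1_l":   {"mean": 2.25, "sd": 0.53},
        "fev1_pct": {"mean": 91,   "sd": 10},
        "ic_tlc":   {"mean": 0.44, "sd": 0.09},
        "dlco_pct": {"mean": 75,   "sd": 20},
        "smwd":     {"mean": 530,  "sd": 81}
      },
      "sgrq": {"median": 10, "q1": 3, "q3": 19},
      "female_frac": 0.56,
      "smoker_frac": 0.53,
      "mmrc2plus_frac": 0.11,
      "mortality_3y": 0.00,
      "markers": {
        "il6":  {"median": 4.0,   "q1": 0.4,   "q3": 17.5},
        "il8":  {"median": 9.0,   "q1": 6.1,   "q3": 16.9},
        "il16": {"median": 314,   "q1": 272,   "q3": 359},
        "tnfa": {"median": 13.1,  "q1": 7.4,   "q3": 19.3},
        "mmp9": {"median": 18088, "q1": 9137,  "q3": 39533},
        "vegf": {"median": 100.5, "q1": 79.8,  "q3": 165.1},
        "parc": {"median": 54177, "q1": 35640, "q3": 62458},
        "mcp1": {"median": 567,   "q1": 435,   "q3": 642}
      }
    },
    {
      "stage": 2,
      "n": 73,
      "clinical": {
        "age":      {"mean": 66,   "sd": 9},
        "bmi":      {"mean": 29,   "sd": 5},
        "fev1_l":   {"mean": 1.54, "sd": 0.41},
        "fev1_pct": {"mean": 61,   "sd": 9},
        "ic_tlc":   {"mean": 0.36, "sd": 0.07},
        "dlco_pct": {"mean": 62,   "sd": 18},
        "smwd":     {"mean": 475,  "sd": 99}
      },
      "sgrq": {"median": 29, "q1": 16, "q3": 42},
      "female_frac": 0.38,
      "smoker_frac": 0.36,
      "mmrc2plus_frac": 0.22,
      "mortality_3y": 0.17,
      "markers": {
        "il6":  {"median": 4.9,   "q1": 0.4,   "q3": 15.3},
        "il8":  {"median": 9.1,   "q1": 6.2,   "q3": 13.9},
        "il16": {"median": 312,   "q1": 209,   "q3": 430},
        "tnfa": {"median": 11.7,  "q1": 7.6,   "q3": 32.4},
        "mmp9": {"median": 10311, "q1": 3531,  "q3": 24100},
        "vegf": {"median": 117.2, "q1": 34.8,  "q3": 238.2},
        "parc": {"median": 51358, "q1": 41459, "q3": 64272},
        "mcp1": {"median": 484,   "q1": 380,   "q3": 586}
      }
    },
    {
      "stage": 3,
      "n": 105,
      "clinical": {
        "age":      {"mean": 67,   "sd": 8},
        "bmi":      {"mean": 27,   "sd": 5},
        "fev1_l":   {"mean": 1.03, "sd": 0.26},
        "fev1_pct": {"mean": 39,   "sd": 6},
        "ic_tlc":   {"mean": 0.28, "sd": 0.06},
        "dlco_pct": {"mean": 48,   "sd": 16},
        "smwd":     {"mean": 425,  "sd": 97}
      },
      "sgrq": {"median": 49, "q1": 34, "q3": 59},
      "female_frac": 0.35,
      "smoker_frac": 0.25,
      "mmrc2plus_frac": 0.65,
      "mortality_3y": 0.41,
      "markers": {
        "il6":  {"median": 5.8,   "q1": 2.9,   "q3": 10.6},
        "il8":  {"median": 9.8,   "q1": 6.6,   "q3": 14.7},
        "il16": {"median": 347,   "q1": 233,   "q3": 594},
        "tnfa": {"median": 19.3,  "q1": 9.5,   "q3": 92.2},
        "mmp9": {"median": 4675,  "q1": 2975,  "q3": 18200},
        "vegf": {"median": 52.0,  "q1": 30.6,  "q3": 154.6},
        "parc": {"median": 50036, "q1": 29334, "q3": 67443},
        "mcp1": {"median": 547,   "q1": 440,   "q3": 775}
      }
    },
    {
      "stage": 4,
      "n": 57,
      "clinical": {
        "age":      {"mean": 63,   "sd": 9},
        "bmi":      {"mean": 25,   "sd": 5},
        "fev1_l":   {"mean": 0.65, "sd": 0.17},
        "fev1_pct": {"mean": 23,   "sd": 4},
        "ic_tlc":   {"mean": 0.19, "sd": 0.06},
        "dlco_pct": {"mean": 35,   "sd": 13},
        "smwd":     {"mean": 314,  "sd": 105}
      },
      "sgrq": {"median": 60, "q1": 45, "q3": 71},
      "female_frac": 0.30,
      "smoker_frac": 0.23,
      "mmrc2plus_frac": 0.83,
      "mortality_3y": 0.60,
      "markers": {
        "il6":  {"median": 9.3,   "q1": 5.9,   "q3": 21.0},
        "il8":  {"median": 11.2,  "q1": 7.3,   "q3": 20.4},
        "il16": {"median": 385,   "q1": 294,   "q3": 635},
        "tnfa": {"median": 26.5,  "q1": 10.6,  "q3": 104.8},
        "mmp9": {"median": 4214,  "q1": 2975,  "q3": 13533},
        "vegf": {"median": 42.1,  "q1": 27.4,  "q3": 83.5},
        "parc": {"median": 54232, "q1": 34358, "q3": 77318},
        "mcp1": {"median": 609,   "q1": 377,   "q3": 762}
      }
    }
  ]
}
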