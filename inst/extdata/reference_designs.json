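{
  "tox_T_1": {
    "problem": "toxicology:normal:1",
    "design": {"support": [0, 1250], "weights": [0.5, 0.5]},
    "note": "T-optimal, plateau Weibull vs constant"
  },
  "tox_T_2": {
    "problem": "toxicology:normal:2",
    "design": {"support": [0, 468.156, 1064.178], "weights": [0.249, 0.498, 0.253]},
    "note": "T-optimal, plateau Weibull vs exponential decay"
  },
  "tox_T_3": {
    "problem": "toxicology:normal:3",
    "design": {"support": [0, 484.197, 963.144, 1250], "weights": [0.092, 0.280, 0.407, 0.221]},
    "note": "T-optimal, plateau Weibull vs Weibull decay"
  },
  "tox_T_4": {
    "problem": "toxicology:normal:4",
    "design": {"support": [0, 468.155, 1064.177], "weights": [0.249, 0.498, 0.253]},
    "note": "T-optimal, plateau Weibull vs plateau exponential"
  },
  "tox_KL_1": {
    "problem": "toxicology:lognormal:1",
    "design": {"support": [0, 1250], "weights": [0.5, 0.5]},
    "note": "KL-optimal (lognormal), vs constant"
  },
  "tox_KL_2": {
    "problem": "toxicology:lognormal:2",
    "design": {"support": [0, 487.447, 1065.370], "weights": [0.271, 0.500, 0.229]},
    "note": "KL-optimal (lognormal), vs exponential decay"
  },
  "tox_KL_3": {
    "problem": "toxicology:lognormal:3",
    "design": {"support": [0, 498.900, 979.719, 1250], "weights": [0.093, 0.290, 0.407, 0.210]},
    "note": "KL-optimal (lognormal), vs Weibull decay"
  },
  "tox_KL_4": {
    "problem": "toxicology:lognormal:4",
    "design": {"support": [0, 487.448, 1065.369], "weights": [0.271, 0.500, 0.229]},
    "note": "KL-optimal (lognormal), vs plateau exponential"
  },
  "tox_mmT": {
    "problem": "toxicology:normal",
    "design": {"support": [0, 433.345, 1027.333, 1250], "weights": [0.214, 0.338, 0.249, 0.200]},
    "value": 0.7747,
    "alpha": [0.493, 0.000, 0.183, 0.324],
    "note": "max-min T-optimal; common efficiency 77.47%"
  },
  "tox_mmKL": {
    "problem": "toxicology:lognormal",
    "design": {"support": [0, 451.530, 1043.591, 1250], "weights": [0.223, 0.342, 0.248, 0.188]},
    "value": 0.7678,
    "alpha": [0.504, 0.001, 0.145, 0.350],
    "note": "max-min KL-optimal; common efficiency 76.78%"
  },
  "tox_P2000": {
    "problem": "toxicology",
    "design": {"support": [0, 270, 350, 450, 580, 750, 970, 1250],
               "weights": [0.125, 0.125, 0.125, 0.125, 0.125, 0.125, 0.125, 0.125]},
    "note": "implemented study design: equal allocation to eight dose groups"
  },
  "mm_mmm_lognormal": {
    "problem": "mm_mmm:lognormal",
    "design": {"support": [0.1, 1.569, 5], "weights": [0.294, 0.500, 0.206]},
    "value": 0.002565090,
    "note": "KL-optimal, lognormal errors"
  },
  "mm_mmm_gamma": {
    "problem": "mm_mmm:gamma",
    "design": {"support": [0.1, 1.569, 5], "weights": [0.287, 0.5119, 0.2011]},
    "value": 0.002564359,
    "note": "KL-optimal, gamma errors"
  },
  "trig_T2": {
    "problem": "trig_poly:1",
    "design": {"support": [-1, -0.6693, 0.1438, 0.9570],
               "weights": [0.2527, 0.4277, 0.2473, 0.0723]},
    "value": 0.001087,
    "note": "T-optimal, exponential vs quadratic"
  },
  "trig_T3": {
    "problem": "trig_poly:2",
    "design": {"support": [-1, -0.7405, -0.1044, 0.6340, 1],
               "weights": [0.1916, 0.3228, 0.2274, 0.1772, 0.0810]},
    "value": 0.005715,
    "note": "T-optimal, exponential vs trigonometric"
  },
  "trig_T23": {
    "problem": "trig_poly",
    "design": {"support": [-1, -0.7034, -0.0196, 0.5725, 1],
               "weights": [0.2279, 0.3822, 0.2167, 0.1133, 0.0599]},
    "value": 0.806,
    "alpha": [0.688, 0.312],
    "note": "max-min T-optimal over both rivals"
  },
  "logistic_KL123": {
    "problem": "logistic4",
    "design": {"support": [0, 0.3598, 1], "weights": [0.6185, 0.2393, 0.1423]},
    "value": 0.619,
    "alpha": [0, 0.409, 0.591],
    "note": "max-min KL-optimal, binomial errors"
  },
  "cubic_3pt": {
    "problem": "cubic_vs_linear",
    "design": {"support": [-0.5, 0.5, 1], "weights": [0.167, 0.5, 0.333]},
    "note": "singular T-optimal design (3 points, 4 cubic parameters)"
  },
  "cubic_4pt": {
    "problem": "cubic_vs_linear",
    "design": {"support": [-1, -0.5, 0.5, 1], "weights": [0.045, 0.211, 0.455, 0.289]},
    "note": "best four-point T-optimal design (optimum is not unique)"
  },
  "constrained_quad": {
    "problem": "constrained_quadratic",
    "design": {"support": [-1, 0, 1], "weights": [0.25, 0.5, 0.25]},
    "note": "T-optimal under the rival norm constraint"
  },
  "dette_m2_rbstT": {
    "problem": "dette:2",
    "design": {"support": [-1, 0.0022, 1], "weights": [0.3137, 0.3712, 0.3151]},
    "value": 0.64,
    "note": "standardized maximin T-optimal, m = 2 (swarm search)"
  },
  "dette_m2_DMS": {
    "problem": "dette:2",
    "design": {"support": [-1, 0, 1], "weights": [0.3125, 0.375, 0.3125]},
    "value": 0.64,
    "note": "standardized maximin T-optimal, m = 2 (analytic)"
  },
  "dette_m3_rbstT": {
    "problem": "dette:3",
    "design": {"support": [-1, -0.4161, 0.4162, 1],
               "weights": [0.1969, 0.3031, 0.3035, 0.1965]},
    "value": 0.6179,
    "note": "standardized maximin T-optimal, m = 3 (swarm search)"
  },
  "dette_m3_DMS": {
    "problem": "dette:3",
    "design": {"support": [-1, -0.4170, 0.4170, 1],
               "weights": [0.1973, 0.3027, 0.3027, 0.1973]},
    "value": 0.6179,
    "note": "standardized maximin T-optimal, m = 3 (analytic)"
  }
}
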