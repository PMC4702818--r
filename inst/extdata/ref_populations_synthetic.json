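{
  "_comment": "SYNTHETIC slider reference populations for testing and examples; not archive statistics.",
  "clash_per_1000_atoms": {
    "direction": "lower-better",
    "em":  [0, 2, 4, 5, 6, 8, 10, 12, 15, 18, 22, 26, 30, 35, 40, 50, 60, 75, 90, 120],
    "all": [0, 1, 2, 3, 4, 5, 6, 8, 10, 12, 14, 17, 20, 24, 28, 34, 40, 50, 65, 85]
  },
  "caca_outlier_fraction": {
    "direction": "lower-better",
    "em":  [0, 0, 0.001, 0.002, 0.004, 0.006, 0.009, 0.012, 0.016, 0.02, 0.025, 0.03, 0.04, 0.05, 0.06, 0.08, 0.1, 0.13, 0.17, 0.22],
    "all": [0, 0, 0, 0.001, 0.002, 0.003, 0.004, 0.006, 0.008, 0.01, 0.013, 0.016, 0.02, 0.025, 0.03, 0.04, 0.05, 0.07, 0.09, 0.12]
  },
  "pp_outlier_fraction": {
    "direction": "lower-better",
    "em":  [0, 0, 0, 0.002, 0.004, 0.007, 0.01, 0.014, 0.018, 0.023, 0.028, 0.034, 0.04, 0.05, 0.06, 0.075, 0.09, 0.11, 0.14, 0.18],
    "all": [0, 0, 0, 0.001, 0.002, 0.004, 0.006, 0.008, 0.011, 0.014, 0.017, 0.021, 0.026, 0.032, 0.04, 0.05, 0.06, 0.075, 0.095, 0.12]
  },
  "rama_outlier_fraction": {
    "direction": "lower-better",
    "em":  [0, 0.002, 0.005, 0.008, 0.012, 0.016, 0.021, 0.027, 0.033, 0.04, 0.048, 0.057, 0.067, 0.078, 0.09, 0.105, 0.12, 0.14, 0.17, 0.21],
    "all": [0, 0.001, 0.002, 0.004, 0.006, 0.009, 0.012, 0.015, 0.019, 0.024, 0.029, 0.035, 0.042, 0.05, 0.06, 0.07, 0.085, 0.1, 0.12, 0.15]
  },
  "atom_inclusion_fraction": {
    "direction": "higher-better",
    "em":  [0.45, 0.52, 0.58, 0.63, 0.67, 0.71, 0.74, 0.77, 0.8, 0.82, 0.84, 0.86, 0.88, 0.9, 0.92, 0.94, 0.95, 0.97, 0.98, 0.995],
    "all": [0.5, 0.57, 0.63, 0.68, 0.72, 0.76, 0.79, 0.82, 0.84, 0.86, 0.88, 0.9, 0.92, 0.93, 0.95, 0.96, 0.97, 0.98, 0.99, 1.0]
  }
}
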