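{
  "description": "Published benchmark figures for five fingerprint SEA models and their multi-voting ensemble, evaluated on a ChEMBL-derived ligand-target test set (newly reported activities held out from training). Rates are as printed (3 decimals); counts are integers.",
  "test_set": {"n_active": 37138, "n_inactive": 42928},
  "true_positives": {
    "atom_pair": 16044,
    "maccs": 15478,
    "morgan": 14176,
    "topological": 14467,
    "pharmacophore": 15594
  },
  "models": {
    "atom_pair":     {"accuracy": 0.692, "precision": 0.817, "sensitivity": 0.432, "specificity": 0.916, "f05": 0.694, "f025": 0.777},
    "maccs":         {"accuracy": 0.682, "precision": 0.802, "sensitivity": 0.417, "specificity": 0.911, "f05": 0.677, "f025": 0.760},
    "morgan":        {"accuracy": 0.676, "precision": 0.826, "sensitivity": 0.382, "specificity": 0.930, "f05": 0.670, "f025": 0.773},
    "topological":   {"accuracy": 0.682, "precision": 0.837, "sensitivity": 0.390, "specificity": 0.934, "f05": 0.681, "f025": 0.784},
    "pharmacophore": {"accuracy": 0.667, "precision": 0.752, "sensitivity": 0.420, "specificity": 0.880, "f05": 0.650, "f025": 0.719},
    "voting1":       {"accuracy": 0.681, "precision": 0.710, "sensitivity": 0.529, "specificity": 0.813, "f05": 0.664, "f025": 0.696},
    "voting2":       {"accuracy": 0.688, "precision": 0.797, "sensitivity": 0.440, "specificity": 0.903, "f05": 0.686, "f025": 0.761},
    "voting3":       {"accuracy": 0.684, "precision": 0.837, "sensitivity": 0.396, "specificity": 0.933, "f05": 0.684, "f025": 0.786},
    "voting4":       {"accuracy": 0.675, "precision": 0.864, "sensitivity": 0.356, "specificity": 0.952, "f05": 0.672, "f025": 0.797},
    "voting5":       {"accuracy": 0.669, "precision": 0.906, "sensitivity": 0.320, "specificity": 0.971, "f05": 0.663, "f025": 0.817}
  },
  "activity_thresholds": {
    "pchembl7":  {"ts": 0.69, "accuracy": 0.568, "precision": 0.958, "sensitivity": 0.072, "specificity": 0.997, "f05": 0.278, "f025": 0.557},
    "pchembl6":  {"ts": 0.69, "accuracy": 0.592, "precision": 0.940, "sensitivity": 0.129, "specificity": 0.993, "f05": 0.417, "f025": 0.687},
    "pchembl5":  {"ts": 0.62, "accuracy": 0.676, "precision": 0.826, "sensitivity": 0.382, "specificity": 0.930, "f05": 0.670, "f025": 0.772}
  },
  "pharmacophore_variants": {
    "p2_coarse":  {"points": [2],    "bins": [[0,2],[2,5],[5,8]],                       "accuracy": 0.513, "precision": 0.479, "sensitivity": 0.567, "specificity": 0.466, "f05": 0.494, "f025": 0.483},
    "p23_coarse": {"points": [2,3],  "bins": [[0,2],[2,5],[5,8]],                       "accuracy": 0.642, "precision": 0.678, "sensitivity": 0.436, "specificity": 0.821, "f05": 0.610, "f025": 0.657},
    "p23_fine":   {"points": [2,3],  "bins": [[2,3],[3,4],[4,5],[5,6],[6,7],[7,20]],    "accuracy": 0.667, "precision": 0.752, "sensitivity": 0.420, "specificity": 0.880, "f05": 0.650, "f025": 0.719}
  },
  "voting_counts": {
    "vote1": {"positives": 27676, "true_positives": 19644, "precision_pct": 71.0},
    "vote5": {"positives": 13122, "true_positives": 11882, "precision_pct": 90.6}
  }
}
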