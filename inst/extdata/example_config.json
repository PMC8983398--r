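{
  "seed": 20260101,
  "scheme": "paired_nt",
  "simulate": {
    "time_points": [0, 1, 3, 7, 28],
    "cells_per_sample": 400,
    "clone_size_exponent": 2.5,
    "persistent_fraction": 0.35,
    "dropout_rate_vdj": 0.15,
    "individuals": [
      {"id": "H1", "baseline": {"T": 0.55, "B": 0.09, "NK": 0.13, "Monocyte": 0.18, "DC": 0.03, "Platelet": 0.02}, "alpha": 400},
      {"id": "H2", "baseline": {"T": 0.55, "B": 0.09, "NK": 0.13, "Monocyte": 0.18, "DC": 0.03, "Platelet": 0.02}, "alpha": 400}
    ],
    "vaccination": {
      "dose_days": [1],
      "monocyte_fold": 1.5,
      "n_induced_clonotypes": 10,
      "induced_base_cells": 2
    }
  },
  "qc": {"min_features": 200, "max_features": 4000, "max_percent_mt": 8},
  "dynamic": {"fold": 2, "min_cells": 3},
  "t_min": 3,
  "diversity": {"v_gene_chains": ["IGH", "TRB"]},
  "phases": [
    {"name": "influenza", "pre_days": [0], "post_days": [1, 3, 7, 28]}
  ]
}
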