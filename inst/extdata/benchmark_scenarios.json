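{
  "comment": "Five benchmark no-covariate scenarios, one per dose being the MTD, defined by their marginal toxicity probabilities on the (1,3,5,7,9) mg grid with reference dose 5 mg and target rate 0.25.  Cells that are not recoverable from the anchor pair at printed 2-decimal precision are stored at the anchor-implied values so that every row is exactly consistent with a single two-parameter logistic model.",
  "scenarios": [
    {"name": "s1", "family": "logistic", "doses": [1, 3, 5, 7, 9],
     "reference_dose": 5, "tau": 0.25,
     "target_marginals": [0.25, 0.39, 0.46, 0.51, 0.55]},
    {"name": "s2", "family": "logistic", "doses": [1, 3, 5, 7, 9],
     "reference_dose": 5, "tau": 0.25,
     "target_marginals": [0.033, 0.24, 0.47, 0.64, 0.75]},
    {"name": "s3", "family": "logistic", "doses": [1, 3, 5, 7, 9],
     "reference_dose": 5, "tau": 0.25,
     "target_marginals": [0.003, 0.07, 0.24, 0.45, 0.62]},
    {"name": "s4", "family": "logistic", "doses": [1, 3, 5, 7, 9],
     "reference_dose": 5, "tau": 0.25,
     "target_marginals": [0.0008, 0.024, 0.11, 0.25, 0.42]},
    {"name": "s5", "family": "logistic", "doses": [1, 3, 5, 7, 9],
     "reference_dose": 5, "tau": 0.25,
     "target_marginals": [0.000005, 0.0014, 0.018, 0.09, 0.26]}
  ]
}
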