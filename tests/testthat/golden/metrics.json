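{
  "n": 100,
  "prevalence": 0.05,
  "roc_auc": 0.98947368421,
  "pauc": 0.089473684211,
  "sens_at_spec": 1,
  "pr_auc": 0.9,
  "f_0.05": 0.8,
  "f_0.1": 0.66666666667,
  "f_0.2": 0.4,
  "f_1": 0.095238095238,
  "mean_f": 0.25768083722
}
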