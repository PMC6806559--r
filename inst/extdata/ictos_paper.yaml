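# Published three-feature ICTOS model (read-only fixture).
# Features are training-cohort z-score standardized values from the
# contrast-enhanced T1 sequence; scores > 0 predict benefit from adding
# induction chemotherapy. Coefficients as printed (rounded to 3 decimals).
coefficients:
  skewness: -0.668
  GLCM_variance: -0.442
  GLRLM_LRHGLE: 0.410
cutoff: 0.0
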