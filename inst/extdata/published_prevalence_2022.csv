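outcome,recency,survey,estimate_pct,ci_low_pct,ci_high_pct
heroin,past_year,probability,0.39,0.30,0.52
heroin,past_year,panel,0.60,0.54,0.67
heroin,past_month,probability,0.26,0.19,0.38
heroin,past_month,panel,0.29,0.25,0.33
heroin,months_2_12,probability,0.13,0.09,0.19
heroin,months_2_12,panel,0.32,0.27,0.37
imf,past_year,probability,0.24,0.18,0.33
imf,past_year,panel,0.74,0.67,0.81
imf,past_month,probability,0.10,0.07,0.16
imf,past_month,panel,0.41,0.36,0.47
imf,months_2_12,probability,0.14,0.08,0.22
imf,months_2_12,panel,0.32,0.28,0.37
either,past_year,probability,0.52,0.40,0.69
either,past_year,panel,1.05,0.97,1.14
either,past_month,probability,0.32,0.23,0.43
either,past_month,panel,0.57,0.51,0.64
either,months_2_12,probability,0.20,0.14,0.30
either,months_2_12,panel,0.48,0.42,0.55
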