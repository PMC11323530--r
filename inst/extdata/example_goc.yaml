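# Worked example: goals-of-care SW-CRT, 8 oncology practices, 5 periods,
# 15 patients per practice-period, minority share 1/3, no secular trend,
# nested exchangeable correlation (ICC 0.1, CAC 0.8), t-based Wald test.
n_clusters: 8
n_periods: 5
cluster_size: 15
p_covariate: 0.333333333333333
baseline_prevalence: 0.35
gammas: [0, 0, 0, 0, 0]
effect_scale: odds_ratio
ote: 1.24
covariate_effect: 0.33
hte: 1.96
icc: 0.1
cac: 0.8
sig_level: 0.05
test: wald_t
mode: power
method: all
seed: 1
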