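# Reference simulation-study configuration: 8 clusters, 5 periods,
# increasing secular trend, 15% baseline outcome prevalence, intermediate
# OTE and HTE effect sizes, simple exchangeable correlation (ICC 0.1).
n_clusters: 8
n_periods: 5
cluster_size: 20
p_covariate: 0.5
baseline_prevalence: 0.15
gammas: [0.0, 0.1, 0.2, 0.3, 0.4]
effect_scale: odds_ratio
ote: 1.68
covariate_effect: 1.5
hte: 1.5
icc: 0.1
cac: 1.0
sig_level: 0.05
test: wald_z
mode: power
method: all
seed: 1
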