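# designs used across tests

# main simulation-study configuration: 15% baseline prevalence, increasing
# secular trend, intermediate OTE/covariate effects
study_design <- function(m = 20, I = 8, p_covariate = 0.5,
                         theta1 = log(1.68), theta2 = log(1.5),
                         theta3 = log(1.5), icc = 0.1, cac = 1, ...) {
  sw_design(n_clusters = I, n_periods = 5, cluster_size = m,
            p_covariate = p_covariate,
            theta0 = log(0.15 / 0.85), gammas = c(0, 0.1, 0.2, 0.3, 0.4),
            theta1 = theta1, theta2 = theta2, theta3 = theta3,
            icc = icc, cac = cac, ...)
}

# goals-of-care worked example: no secular trend, nested correlation,
# t-based test with I - 4 = 4 degrees of freedom
goc_example_design <- function(m = 15) {
  sw_design(n_clusters = 8, n_periods = 5, cluster_size = m,
            p_covariate = 1 / 3,
            theta0 = log(0.35 / 0.65), gammas = rep(0, 5),
            theta1 = log(1.24), theta2 = log(0.33), theta3 = log(1.96),
            icc = 0.1, cac = 0.8, test = "wald_t")
}

# small design for dense-oracle comparisons
tiny_design <- function(icc = 0.08, cac = 0.6) {
  sw_design(n_clusters = 4, n_periods = 3, cluster_size = 4,
            p_covariate = 0.5,
            theta0 = log(0.3 / 0.7), gammas = c(0, 0.1, 0.2),
            theta1 = log(1.5), theta2 = log(1.3), theta3 = log(1.8),
            icc = icc, cac = cac)
}
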