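# published predicted-power grids (three-decimal values) for the main
# simulation study: 50% covariate prevalence, OTE log(1.68), cluster sizes
# 20..120, HTE log(1.5) and log(2); rows GEE / GEE-KC / GEE-MD.
printed_power_grids <- list(
  # I = 8, simple exchangeable (ICC 0.1)
  I8_cac1 = list(
    hte_1.5 = rbind(GEE = c(.252, .445, .606, .729, .819, .882),
                    `GEE-KC` = c(.220, .388, .536, .657, .752, .824),
                    `GEE-MD` = c(.193, .336, .469, .583, .679, .756)),
    hte_2 = rbind(GEE = c(.595, .875, .968, .992, .998, 1.000),
                  `GEE-KC` = c(.526, .816, .938, .981, .995, .999),
                  `GEE-MD` = c(.459, .747, .895, .960, .985, .995))),
  # I = 8, nested exchangeable (ICC 0.1, CAC 0.8)
  I8_cac0.8 = list(
    hte_1.5 = rbind(GEE = c(.251, .444, .604, .727, .816, .879),
                    `GEE-KC` = c(.220, .387, .534, .654, .749, .821),
                    `GEE-MD` = c(.192, .336, .467, .581, .676, .753)),
    hte_2 = rbind(GEE = c(.595, .874, .967, .992, .998, 1.000),
                  `GEE-KC` = c(.525, .815, .937, .981, .994, .998),
                  `GEE-MD` = c(.459, .746, .894, .959, .985, .995))),
  I20_cac1 = list(
    hte_1.5 = rbind(GEE = c(.531, .821, .941, .982, .995, .999),
                    `GEE-KC` = c(.506, .797, .927, .976, .993, .998),
                    `GEE-MD` = c(.481, .771, .911, .968, .989, .997)),
    hte_2 = rbind(GEE = c(.936, .998, 1, 1, 1, 1),
                  `GEE-KC` = c(.921, .997, 1, 1, 1, 1),
                  `GEE-MD` = c(.904, .996, 1, 1, 1, 1))),
  I20_cac0.8 = list(
    hte_1.5 = rbind(GEE = c(.530, .820, .940, .982, .995, .999),
                    `GEE-KC` = c(.505, .795, .926, .975, .992, .998),
                    `GEE-MD` = c(.481, .770, .910, .967, .989, .996)),
    hte_2 = rbind(GEE = c(.935, .998, 1, 1, 1, 1),
                  `GEE-KC` = c(.921, .997, 1, 1, 1, 1),
                  `GEE-MD` = c(.904, .996, 1, 1, 1, 1))),
  I40_cac1 = list(
    hte_1.5 = rbind(GEE = c(.821, .983, .999, 1, 1, 1),
                    `GEE-KC` = c(.810, .980, .998, 1, 1, 1),
                    `GEE-MD` = c(.798, .977, .998, 1, 1, 1)),
    hte_2 = rbind(GEE = c(.998, 1, 1, 1, 1, 1),
                  `GEE-KC` = c(.998, 1, 1, 1, 1, 1),
                  `GEE-MD` = c(.998, 1, 1, 1, 1, 1))),
  I40_cac0.8 = list(
    hte_1.5 = rbind(GEE = c(.821, .982, .999, 1, 1, 1),
                    `GEE-KC` = c(.809, .979, .998, 1, 1, 1),
                    `GEE-MD` = c(.797, .976, .998, 1, 1, 1)),
    hte_2 = rbind(GEE = c(.998, 1, 1, 1, 1, 1),
                  `GEE-KC` = c(.998, 1, 1, 1, 1, 1),
                  `GEE-MD` = c(.998, 1, 1, 1, 1, 1))))
grid_cluster_sizes <- c(20, 40, 60, 80, 100, 120)

# published required cluster sizes (target 80% predicted power) and the
# predicted power at the returned size, GEE method only; columns:
# theta1, theta3, prevalence, size, power
printed_gee_sizes <- list(
  cac1 = data.frame(
    theta1 = log(c(1.35, 1.35, 1.35, 1.35, 1.68, 1.68, 1.68, 1.68)),
    theta3 = log(c(1.5, 1.5, 2, 2, 1.5, 1.5, 2, 2)),
    prevalence = c(.3, .5, .3, .5, .3, .5, .3, .5),
    size = c(110, 98, 40, 34, 110, 96, 40, 34),
    power = c(.801, .803, .827, .810, .807, .804, .831, .818)),
  cac0.8 = data.frame(
    theta1 = log(c(1.35, 1.35, 1.35, 1.35, 1.68, 1.68, 1.68, 1.68)),
    theta3 = log(c(1.5, 1.5, 2, 2, 1.5, 1.5, 2, 2)),
    prevalence = c(.3, .5, .3, .5, .3, .5, .3, .5),
    size = c(120, 100, 40, 34, 110, 96, 40, 34),
    power = c(.829, .806, .825, .809, .804, .801, .830, .817)))

# literal dense transcription of the displayed variance formulas, used as
# the independent oracle against the optimized engine
dense_variance_oracle <- function(design, Fi_kind = c("identity", "kc", "md")) {
  Fi_kind <- match.arg(Fi_kind)
  dm <- sw_design_matrices(design)
  J <- design$n_periods; m <- design$cluster_size; n <- J * m
  R <- corr_matrix(sw_correlation(J, m, design$icc, design$cac))
  cl <- lapply(dm$cluster_pattern, function(p) dm$patterns[[p]])
  Sig <- lapply(cl, function(x) diag(1 / sqrt(x$A)) %*% R %*% diag(1 / sqrt(x$A)))
  bread <- solve(Reduce(`+`, Map(function(x, S)
    t(x$M) %*% solve(S) %*% x$M, cl, Sig)))
  meat <- Reduce(`+`, Map(function(x, S) {
    Sinv <- solve(S)
    H <- diag(x$A) %*% x$M %*% bread %*% t(x$M) %*% Sinv %*% diag(1 / x$A)
    Fi <- switch(Fi_kind,
      identity = diag(n),
      md = solve(diag(n) - H),
      kc = {
        es <- eigen(diag(n) - H)
        Re(es$vectors %*% diag(es$values^(-0.5)) %*% solve(es$vectors))
      })
    Omega_inv <- Sinv %*% diag(1 / x$A) %*% Fi %*% diag(x$A) %*% S %*%
      diag(x$A) %*% t(Fi) %*% diag(1 / x$A) %*% Sinv
    t(x$M) %*% Omega_inv %*% x$M
  }, cl, Sig))
  bread %*% meat %*% bread
}
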