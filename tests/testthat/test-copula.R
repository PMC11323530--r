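test_that("pairwise latent correlation solves the copula equation", {
  expect_equal(copula_latent_corr(0.3, 0.6, 0), 0)
  xi <- copula_latent_corr(0.15, 0.15, 0.1)
  # symmetry in the margins
  expect_equal(copula_latent_corr(0.2, 0.7, 0.05),
               copula_latent_corr(0.7, 0.2, 0.05), tolerance = 1e-10)
  # solved joint probability reproduces the target
  p11 <- 0.1 * 0.15 * (1 - 0.15) + 0.15^2
  expect_equal(swhte:::pbinorm(qnorm(0.15), qnorm(0.15), xi), p11,
               tolerance = 1e-7)
})

test_that("solved latent correlation matches a Monte-Carlo bivariate oracle", {
  xi <- copula_latent_corr(0.15, 0.15, 0.1)
  set.seed(11)
  n <- 4e5
  z1 <- rnorm(n); z2 <- xi * z1 + sqrt(1 - xi^2) * rnorm(n)
  y1 <- z1 <= qnorm(0.15); y2 <- z2 <= qnorm(0.15)
  r_emp <- cor(y1, y2)
  mc_se <- sqrt((1 - 0.1^2)^2 / n) * 2   # generous bound on the corr SE
  expect_lt(abs(r_emp - 0.1), 3 * max(mc_se, 1 / sqrt(n) * 3))
})

test_that("infeasible pairwise targets are rejected with the bounds named", {
  expect_error(copula_latent_corr(0.05, 0.05, 0.9), NA)
  expect_error(copula_latent_corr(0.05, 0.95, 0.9), "Frechet")
})

test_that("eigenvalue repair floors the spectrum and keeps the unit diagonal", {
  # symmetric matrix with a small negative eigenvalue
  Q <- qr.Q(qr(matrix(c(1, 2, 0, -1, 1, 1, 1, 0, 1), 3)))
  bad <- Q %*% diag(c(1.5, 1.49, -0.01)) %*% t(Q)
  d <- sqrt(diag(bad)); bad <- bad / (d %o% d)  # unit diagonal, still indefinite
  expect_lt(min(eigen(bad, symmetric = TRUE)$values), 0)
  rep_out <- repair_psd(bad, 1e-6)
  expect_true(rep_out$repaired)
  expect_equal(diag(rep_out$mat), rep(1, 3))
  expect_gte(min(eigen(rep_out$mat, symmetric = TRUE)$values), 0)
  expect_gt(rep_out$max_change, 0)
  # a PSD input passes through untouched
  ok <- diag(3); ok[1, 2] <- ok[2, 1] <- 0.3
  expect_false(repair_psd(ok)$repaired)
  expect_equal(repair_psd(ok)$mat, ok)
})

test_that("latent matrices reuse cached pairwise solutions per pattern", {
  d <- study_design(m = 10)
  lat <- sw_latent(d)
  # distinct (mu, mu', within/between) combinations bound the cache size:
  # with k distinct marginal means across patterns, at most choose(k,2)+k
  # unordered pairs for each of the two lag classes
  J <- d$n_periods
  dm <- sw_design_matrices(d)
  k <- length(unique(round(unlist(lapply(dm$patterns, `[[`, "mu")), 12)))
  expect_lte(lat$n_xi_solved, 2 * (choose(k, 2) + k))
  expect_length(lat$patterns, J - 1)
  # independence: latent matrix is the identity (factor lower-triangular identity)
  d0 <- sw_design(8, 5, 6, 0.5, 0, rep(0, 5), 0.2, 0.1, 0.3, icc = 0)
  lat0 <- sw_latent(d0)
  expect_equal(lat0$patterns[[1]]$factor, diag(30), tolerance = 1e-6)
})

test_that("a homogeneous exchangeable design needs a single latent value", {
  # all means equal, simple exchangeable: one distinct off-diagonal entry
  d <- sw_design(4, 3, 4, 0.5, qlogis(0.3), rep(0, 3), 0, 0, 0, 0.1, 1)
  lat <- sw_latent(d)
  Xi <- tcrossprod(lat$patterns[[1]]$factor)
  off <- unique(round(Xi[upper.tri(Xi)], 8))
  expect_length(off, 1)
  expect_equal(lat$n_xi_solved, 1)
})

test_that("simulation is reproducible and aligned with the design layout", {
  d <- study_design(m = 6)
  lat <- sw_latent(d)
  a <- sw_simulate(d, 2, seed = 99, latent = lat)
  b <- sw_simulate(d, 2, seed = 99, latent = lat)
  expect_identical(a, b)
  expect_setequal(unique(a$Y), c(0, 1))
  expect_equal(nrow(a), 2 * 8 * 5 * 6)
  # W column matches the balanced schedule; X counts match the allocation
  lay <- sw_layout(d)
  one <- dplyr::filter(a, replicate == 1)
  Wmat <- with(unique(one[, c("cluster", "period", "W")]),
               matrix(W, nrow = 8, byrow = TRUE))
  expect_equal(Wmat, lay$W)
  cnt <- dplyr::count(dplyr::filter(one, X == 1), cluster, period)
  expect_true(all(cnt$n == lay$x_count))
})

test_that("simulated outcomes recover the marginal means and correlations", {
  d <- study_design(m = 8, icc = 0.1, cac = 0.8)
  lat <- sw_latent(d)
  nrep <- 400                    # 3200 cluster draws
  dat <- sw_simulate(d, nrep, seed = 5, latent = lat)
  dm <- sw_design_matrices(d)
  # cell means: cluster 1 (pattern 1), every period x covariate cell
  c1 <- dplyr::filter(dat, cluster == 1)
  mu1 <- dm$patterns[[1]]$mu
  cell <- dplyr::summarise(
    dplyr::group_by(c1, period, X), y = mean(Y), n = dplyr::n(),
    .groups = "drop")
  idx <- (cell$period - 1) * d$cluster_size + ifelse(cell$X == 1, d$cluster_size, 1)
  mu_cell <- mu1[idx]
  se_cell <- sqrt(mu_cell * (1 - mu_cell) / cell$n)
  expect_true(all(abs(cell$y - mu_cell) < 4 * se_cell))
  # within-period and cross-period correlations (pooled pairs, cluster 1)
  Y <- matrix(dplyr::filter(dat, cluster == 1)$Y, ncol = nrep)
  r <- (Y - mu1) / sqrt(mu1 * (1 - mu1))
  within <- cor(r[1, ], r[2, ])          # same period, both X = 0
  cross <- cor(r[1, ], r[1 + d$cluster_size, ])  # adjacent periods
  mc <- 3.5 / sqrt(nrep)
  expect_lt(abs(within - d$icc), mc)
  expect_lt(abs(cross - d$icc * d$cac), mc)
})
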