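test_that("balanced layout follows the uni-directional crossover convention", {
  d <- study_design()
  lay <- sw_layout(d)
  expect_equal(rowSums(lay$W), c(4, 4, 3, 3, 2, 2, 1, 1))
  expect_true(all(lay$W[, 1] == 0))
  expect_true(all(lay$W[, 5] == 1))
  # each step switches exactly I / (J - 1) = 2 clusters
  expect_equal(colSums(lay$W), c(0, 2, 4, 6, 8))
  # rows non-decreasing
  expect_true(all(apply(lay$W, 1, function(w) all(diff(w) >= 0))))
})

test_that("covariate allocation is deterministic and exact per cluster-period", {
  expect_equal(sw_layout(study_design(m = 20, p_covariate = 0.5))$x_count, 10)
  expect_equal(sw_layout(study_design(m = 15, p_covariate = 0.33))$x_count, 5)
  lay <- sw_layout(study_design(m = 20, p_covariate = 0.3))
  expect_equal(sum(lay$covariate), 5 * 6)  # 6 per period, 5 periods
})

test_that("invalid designs are rejected with informative messages", {
  expect_error(study_design(I = 9), "divisible")
  expect_error(study_design(m = 20, p_covariate = 0.01), "degenerate covariate")
  expect_error(
    sw_design(8, 5, 20, 0.5, 0, c(0.1, 0, 0, 0, 0), 0, 0, 0, 0.1),
    "gammas\\[1\\]")
  expect_error(study_design(icc = -0.9), "not positive definite|inadmissible")
  # multiple problems reported together
  err <- tryCatch(sw_design(9, 5, -3, 2, 0, c(0, 0, 0, 0, 0), 0, 0, 0, 0.1),
                  error = function(e) conditionMessage(e))
  expect_match(err, "divisible")
  expect_match(err, "p_covariate")
})

test_that("marginal means follow the inverse-logit of the linear predictor", {
  d0 <- sw_design(8, 5, 20, 0.5, log(0.15 / 0.85), rep(0, 5), 0, 0, 0, 0.1)
  expect_equal(sw_marginal_mean(d0, 3, 1, 1), 0.15)
  d <- goc_example_design()
  # minority control rate ~15%, minority treated rate ~30%
  expect_equal(sw_marginal_mean(d, 1, 0, 1), 0.151, tolerance = 0.005)
  expect_equal(sw_marginal_mean(d, 1, 1, 1), 0.302, tolerance = 0.005)
  expect_error(sw_marginal_mean(d, 6, 0, 0), "period")
})

test_that("design matrices encode the model exactly", {
  d <- study_design()
  dm <- sw_design_matrices(d)
  for (p in dm$patterns) {
    expect_equal(ncol(p$M), d$n_periods + 3)
    # logit(u) = M theta to machine precision
    expect_equal(qlogis(p$mu), drop(p$M %*% dm$theta), tolerance = 1e-12)
    expect_equal(p$A, p$mu * (1 - p$mu))
    # first-period rows: period-indicator block all zero
    first <- p$M[seq_len(d$cluster_size), 2:d$n_periods]
    expect_true(all(first == 0))
  }
  # number of distinct patterns is J - 1 and multiplicities sum to I
  expect_length(dm$patterns, d$n_periods - 1)
  expect_equal(sum(vapply(dm$patterns, `[[`, 0, "n_clusters")), d$n_clusters)
})

test_that("untreated periods have zero W and interaction columns regardless of X", {
  d <- study_design()
  dm <- sw_design_matrices(d)
  # last pattern crosses over at the final period: periods 1..4 untreated
  late <- dm$patterns[[length(dm$patterns)]]
  untreated <- seq_len(4 * d$cluster_size)
  expect_true(all(late$M[untreated, "W"] == 0))
  expect_true(all(late$M[untreated, "W:X"] == 0))
  expect_true(any(late$M[untreated, "X"] == 1))
})

test_that("within-period permutation of individuals leaves variances unchanged", {
  d <- tiny_design()
  base <- sw_variance(d, "GEE-KC", engine = "dense")$full_cov
  dm <- sw_design_matrices(d)
  m <- d$cluster_size
  set.seed(42)
  perm <- unlist(lapply(0:(d$n_periods - 1), function(j) j * m + sample(m)))
  dm_perm <- dm
  dm_perm$patterns <- lapply(dm$patterns, function(p) {
    list(M = p$M[perm, ], mu = p$mu[perm], A = p$A[perm],
         n_clusters = p$n_clusters)
  })
  perm_cov <- swhte:::variance_dense(d, dm_perm, "GEE-KC")
  expect_equal(perm_cov, base, tolerance = 1e-10)
})

test_that("a custom schedule overrides the balanced convention", {
  W <- rbind(c(0, 1, 1), c(0, 1, 1), c(0, 0, 1), c(0, 0, 1))
  d <- sw_design(4, 3, 6, 0.5, 0, c(0, 0, 0), 0.2, 0.1, 0.3, 0.05,
                 schedule = W)
  expect_equal(sw_layout(d)$W, W)
  expect_error(
    sw_design(4, 3, 6, 0.5, 0, c(0, 0, 0), 0.2, 0.1, 0.3, 0.05,
              schedule = W[, c(2, 1, 3)]),
    "column 1")
})
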