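sim_one <- function(design, seed) {
  sw_simulate(design, 1, seed = seed)
}

test_that("independence working correlation reproduces pooled logistic MLE", {
  d <- study_design(m = 20)
  dat <- sim_one(d, 3)
  fit <- sw_gee(dat, working = "independence")
  g <- stats::glm(Y ~ factor(period) + W + X + W:X, binomial, data = dat)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$theta - unname(coef(g)))), 1e-6)
  expect_equal(fit$alpha_hat, 0)
})

test_that("the estimating equations are solved at the returned estimates", {
  d <- study_design(m = 20, icc = 0.1, cac = 0.8)
  for (s in 1:3) {
    fit <- sw_gee(sim_one(d, s), working = "nested")
    expect_true(fit$converged)
    expect_lt(fit$max_score, 1e-3)
  }
})

test_that("naive covariance equals the design-stage formula at the fitted values", {
  d <- study_design(m = 20)
  fit <- sw_gee(sim_one(d, 8), working = "nested")
  # same formula, same inputs: rebuild the design at the fitted coefficients
  # and estimated correlation, then compare model-based covariances
  th <- unname(fit$theta)
  d_hat <- sw_design(8, 5, 20, 0.5, theta0 = th[1], gammas = c(0, th[2:5]),
                     theta1 = th[6], theta2 = th[7], theta3 = th[8],
                     icc = fit$alpha_hat, cac = fit$rho_hat)
  expect_equal(unname(fit$naive_cov), unname(sw_variance(d_hat, "GEE")$full_cov),
               tolerance = 1e-8)
})

test_that("empirical standard errors order as robust <= KC <= MD on the target", {
  d <- study_design(m = 40)
  for (s in 1:3) {
    fit <- sw_gee(sim_one(d, s + 20), working = "exchangeable")
    q <- length(fit$theta)
    expect_lte(fit$robust_cov[q, q], fit$kc_cov[q, q])
    expect_lte(fit$kc_cov[q, q], fit$md_cov[q, q])
  }
})

test_that("moment estimation recovers the correlation parameters on average", {
  d <- study_design(m = 40, I = 8, icc = 0.1, cac = 1)
  lat <- sw_latent(d)
  set.seed(31)
  ah <- replicate(30, sw_gee(sw_simulate(d, 1, latent = lat),
                             working = "exchangeable")$alpha_hat)
  # moment ICC estimates centre near the generating value (small-I bias
  # allowed: tolerance 0.03 on a true value of 0.1)
  expect_lt(abs(mean(ah) - 0.1), 0.03)
})

test_that("interaction estimates recover the generating effect", {
  d <- study_design(m = 40, I = 8, p_covariate = 0.5, theta3 = log(1.5))
  lat <- sw_latent(d)
  set.seed(17)
  th3 <- replicate(60, {
    fit <- sw_gee(sw_simulate(d, 1, latent = lat), working = "exchangeable")
    if (fit$converged) unname(fit$theta[8]) else NA_real_
  })
  th3 <- th3[!is.na(th3)]
  mc_se <- sd(th3) / sqrt(length(th3))
  expect_lt(abs(mean(th3) - log(1.5)), 3 * mc_se)
})

test_that("the reduced model targets the treatment effect", {
  d <- study_design(m = 20, theta1 = log(1.35), theta2 = 0, theta3 = 0)
  fit <- sw_gee(sim_one(d, 5), working = "exchangeable", model = "ote")
  expect_length(fit$theta, d$n_periods + 1)
  expect_equal(names(fit$theta)[length(fit$theta)], "W")
  tst <- sw_gee_test(fit, "naive")
  expect_equal(tst$term, "W")
})

test_that("degenerate inputs are flagged or rejected", {
  d <- study_design(m = 6)
  dat <- sim_one(d, 1)
  dat$Y <- 1
  expect_error(sw_gee(dat), "both outcome values")
})

test_that("Wald test decision follows the statistic", {
  fake <- structure(list(theta = c(`(Intercept)` = 0, `W:X` = 0),
                         naive_cov = diag(c(1, 1)), n_clusters = 8),
                    class = "sw_gee")
  expect_false(sw_gee_test(fake, "naive")$reject)
  fake$theta[2] <- 1; fake$naive_cov[2, 2] <- 1e-8
  expect_true(sw_gee_test(fake, "naive")$reject)
  # t critical value is larger: a borderline z rejection can fail under t
  fake$naive_cov[2, 2] <- (1 / 2.2)^2
  expect_true(sw_gee_test(fake, "naive", test = "wald_z")$reject)
  expect_false(sw_gee_test(fake, "naive", test = "wald_t", df = 4)$reject)
})

test_that("tidy and glance summarise a fit", {
  d <- study_design(m = 20)
  fit <- sw_gee(sim_one(d, 12), working = "nested")
  td <- generics::tidy(fit, se = "kc")
  expect_s3_class(td, "tbl_df")
  expect_equal(td$term[nrow(td)], "W:X")
  expect_true(all(c("estimate", "std.error", "p.value") %in% names(td)))
  gl <- generics::glance(fit)
  expect_equal(gl$working, "nested")
  expect_true(gl$converged)
})
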