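test_that("Wald power formula behaves at its boundary cases", {
  expect_equal(power_wald(0, 1, 0.05), 0.025)
  expect_gt(power_wald(0.5, 1e-10), 1 - 1e-12)
  # t-based power never exceeds z-based power in the relevant region
  d <- study_design()
  for (m in c(20, 60, 120)) {
    v <- sw_variance(study_design(m = m), "GEE")$var_hte
    expect_lte(power_wald(log(1.5), v, test = "wald_t", df = 4),
               power_wald(log(1.5), v))
  }
})

test_that("predicted power increases in cluster size, clusters and effect size", {
  pw_m <- sw_power_curve(study_design(), c(20, 40, 80, 120), "GEE")
  expect_true(all(diff(pw_m$predicted_power) > 0))
  pw_I <- vapply(c(8, 20, 40), function(I)
    sw_power(study_design(I = I), "GEE-MD")$predicted_power, numeric(1))
  expect_true(all(diff(pw_I) > 0))
  d <- study_design()
  pw_d <- vapply(c(1.2, 1.5, 2, 3), function(orr)
    sw_power(swhte:::with_theta3(d, log(orr)), "GEE")$predicted_power,
    numeric(1))
  expect_true(all(diff(pw_d) > 0))
})

test_that("cluster-size search returns the grid minimum and round-trips", {
  d <- study_design(p_covariate = 0.3, theta1 = log(1.35))
  res <- sw_find_cluster_size(d, 0.8, "GEE")
  expect_equal(res$cluster_size, 110L)
  expect_gte(res$predicted_power, 0.8)
  # previous grid point is below target
  expect_lt(sw_power(swhte:::with_cluster_size(d, 100), "GEE")$predicted_power, 0.8)
  # default grid steps follow the covariate prevalence
  expect_equal(swhte:::default_size_step(0.3), 10)
  expect_equal(swhte:::default_size_step(0.5), 2)
  expect_equal(swhte:::default_size_step(1 / 3), 3)
  expect_equal(swhte:::default_size_step(0.37), 1L)
  # a larger effect size never needs a larger cluster size
  d2 <- swhte:::with_theta3(d, 2 * d$theta3)
  expect_lte(sw_find_cluster_size(d2, 0.8, "GEE")$cluster_size, res$cluster_size)
})

test_that("cluster-number search respects the schedule constraint", {
  d <- study_design(m = 20)
  expect_equal(
    sw_find_n_clusters(d, 0.8, "GEE", candidates = c(8, 20, 40))$n_clusters, 40L)
  expect_equal(
    sw_find_n_clusters(study_design(m = 120), 0.8, "GEE",
                       candidates = c(8, 20, 40))$n_clusters, 8L)
  expect_equal(
    sw_find_n_clusters(d, 0, "GEE", candidates = c(8, 20, 40))$n_clusters, 8L)
  expect_error(sw_find_n_clusters(d, 0.8, "GEE", candidates = c(9, 20)),
               "multiples")
  expect_error(sw_find_n_clusters(d, 0.9999, "GEE", candidates = c(8)),
               "not reached")
})

test_that("minimal detectable effect search matches the power function", {
  d <- goc_example_design()
  res <- sw_find_mde(d, 0.8, "GEE", resolution = 0.01)
  expect_gte(res$predicted_power, 0.8)
  # one resolution step lower misses the target
  below <- sw_power(swhte:::with_theta3(d, log(res$mde_or - 0.01)),
                    "GEE")$predicted_power
  expect_lt(below, 0.8)
  # at target alpha/2 the null effect (odds ratio 1) suffices
  res0 <- sw_find_mde(d, 0.02, "GEE")
  expect_equal(res0$mde_or, 1)
})

test_that("search failures report the power at the ceiling", {
  d <- study_design()
  expect_error(sw_find_cluster_size(d, 0.999999, "GEE-MD", max_size = 60),
               "not reached")
  expect_error(sw_find_mde(d, 0.9999999, "GEE", max_or = 2), "not reached")
})

test_that("power curve sweep carries methods and sizes for plotting", {
  curve <- sw_power_curve(study_design(), c(20, 40), "all")
  expect_equal(nrow(curve), 6)
  expect_s3_class(curve, "sw_power_curve")
  p <- ggplot2::autoplot(curve)
  expect_s3_class(p, "ggplot")
})
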