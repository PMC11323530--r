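#' Predicted power of the two-sided Wald test for the HTE
#'
#' Given the effect size \eqn{\delta} and the predicted variance
#' \eqn{v = \mathrm{Var}(\hat\theta_3)}, the normal-based power is
#' \deqn{\varphi = \Phi\!\left(\delta / \sqrt{v} - z_{1 - \alpha/2}\right),}
#' and the t-based analogue (recommended with few clusters) replaces
#' \eqn{\Phi} and the quantile by their t counterparts with `df` degrees of
#' freedom.
#'
#' @param delta Effect size on the log odds-ratio scale (HTE under the
#'   alternative).
#' @param var_hte Predicted variance of the interaction estimator.
#' @param sig_level Two-sided significance level.
#' @param test `"wald_z"` or `"wald_t"`.
#' @param df Degrees of freedom for `"wald_t"`.
#' @return Power in (0, 1). Vectorised over `delta` and `var_hte`.
#' @export
power_wald <- function(delta, var_hte, sig_level = 0.05,
                       test = c("wald_z", "wald_t"), df = NULL) {
  test <- match.arg(test)
  stopifnot(all(var_hte > 0), sig_level > 0, sig_level < 1)
  z <- delta / sqrt(var_hte)
  if (test == "wald_z") {
    stats::pnorm(z - stats::qnorm(1 - sig_level / 2))
  } else {
    stopifnot(!is.null(df), df > 0)
    stats::pt(z - stats::qt(1 - sig_level / 2, df), df)
  }
}

methods_vec <- function(method) {
  if (length(method) == 1 && tolower(method) == "all") {
    c("GEE", "GEE-KC", "GEE-MD")
  } else {
    vapply(method, normalize_method, character(1), USE.NAMES = FALSE)
  }
}

#' Predicted HTE power for a stepped-wedge design
#'
#' Computes the design-stage variance of the interaction estimator under one
#' or more variance methods and converts it to predicted power via the
#' two-sided Wald test at the design's significance level.
#'
#' @param design An [sw_design()] object.
#' @param method `"all"` (default) or any subset of
#'   `c("GEE", "GEE-KC", "GEE-MD")`.
#' @param delta Effect size used in the power formula; defaults to the
#'   design's `theta3`.
#' @return A tibble with one row per method: design descriptors, `se_hte`
#'   (predicted standard error of the HTE estimator) and `predicted_power`.
#' @export
sw_power <- function(design, method = "all", delta = design$theta3) {
  rows <- lapply(methods_vec(method), function(mth) {
    v <- sw_variance(design, mth)
    tibble::tibble(
      method = mth,
      n_clusters = design$n_clusters, n_periods = design$n_periods,
      cluster_size = design$cluster_size, p_covariate = design$p_covariate,
      icc = design$icc, cac = design$cac,
      hte = delta, var_hte = v$var_hte, se_hte = sqrt(v$var_hte),
      predicted_power = power_wald(delta, v$var_hte, design$sig_level,
                                   design$test, design$t_df)
    )
  })
  dplyr::bind_rows(rows)
}

# default search grid step: smallest s <= 10 with s * p integral, else 1;
# keeps round(m * p) exact along the grid (10 for 30%, 2 for 50%, 3 for 1/3)
default_size_step <- function(p_covariate) {
  for (s in 1:10) {
    if (abs(s * p_covariate - round(s * p_covariate)) < 1e-8) return(s)
  }
  1L
}

with_cluster_size <- function(design, m) {
  sw_design(design$n_clusters, design$n_periods, m, design$p_covariate,
            design$theta0, design$gammas, design$theta1, design$theta2,
            design$theta3, design$icc, design$cac, design$sig_level,
            design$test, design$t_df, design$schedule)
}

with_n_clusters <- function(design, I) {
  sw_design(I, design$n_periods, design$cluster_size, design$p_covariate,
            design$theta0, design$gammas, design$theta1, design$theta2,
            design$theta3, design$icc, design$cac, design$sig_level,
            design$test, if (design$test == "wald_t") max(I - 4, 1) else design$t_df,
            schedule = NULL)
}

with_theta3 <- function(design, theta3) {
  sw_design(design$n_clusters, design$n_periods, design$cluster_size,
            design$p_covariate, design$theta0, design$gammas, design$theta1,
            design$theta2, theta3, design$icc, design$cac, design$sig_level,
            design$test, design$t_df, design$schedule)
}

#' Smallest cluster size reaching a target predicted power
#'
#' Searches the grid `step, 2*step, ...` for the smallest per-period cluster
#' size whose predicted HTE power is at least `target_power`. The default
#' step is the smallest integer (up to 10) that makes
#' `cluster_size * p_covariate` integral — 10 for 30% prevalence, 2 for 50%,
#' 3 for 1/3 — so the deterministic covariate allocation is exact along the
#' grid.
#'
#' @param design An [sw_design()] object; its `cluster_size` is ignored.
#' @param target_power Target predicted power (default 0.8).
#' @param method `"all"` or subset of `c("GEE", "GEE-KC", "GEE-MD")`.
#' @param step Grid step; `NULL` for the default rule.
#' @param max_size Search ceiling; exceeding it is an error reporting the
#'   power reached at the ceiling.
#' @return Tibble with one row per method: `cluster_size` (the grid minimum)
#'   and `predicted_power` at that size.
#' @export
sw_find_cluster_size <- function(design, target_power = 0.8, method = "all",
                                 step = NULL, max_size = 10000) {
  if (is.null(step)) step <- default_size_step(design$p_covariate)
  rows <- lapply(methods_vec(method), function(mth) {
    m <- step
    repeat {
      pw <- tryCatch(
        sw_power(with_cluster_size(design, m), mth)$predicted_power,
        error = function(e) NA_real_)   # e.g. degenerate covariate at tiny m
      if (!is.na(pw) && pw >= target_power) break
      m <- m + step
      if (m > max_size) {
        stop(sprintf(
          "target power %.3f not reached by cluster_size <= %d (method %s; power at ceiling = %.4f)",
          target_power, max_size, mth, if (is.na(pw)) NA else pw), call. = FALSE)
      }
    }
    tibble::tibble(method = mth, cluster_size = as.integer(m),
                   target_power = target_power, predicted_power = pw)
  })
  dplyr::bind_rows(rows)
}

#' Smallest number of clusters reaching a target predicted power
#'
#' Searches candidate numbers of clusters (by default multiples of
#' `n_periods - 1`, the balanced-schedule constraint) for the smallest one
#' whose predicted HTE power reaches `target_power`.
#'
#' @param design An [sw_design()] object; its `n_clusters` is ignored.
#' @param target_power Target predicted power.
#' @param method `"all"` or subset.
#' @param candidates Increasing vector of candidate cluster numbers; default
#'   multiples of `n_periods - 1` up to `max_clusters`.
#' @param max_clusters Ceiling for the default candidate set.
#' @return Tibble with one row per method.
#' @export
sw_find_n_clusters <- function(design, target_power = 0.8, method = "all",
                               candidates = NULL, max_clusters = 1000) {
  steps <- design$n_periods - 1
  if (is.null(candidates)) candidates <- seq(steps, max_clusters, by = steps)
  if (any(candidates %% steps != 0)) {
    stop("candidates must be multiples of n_periods - 1 = ", steps, call. = FALSE)
  }
  rows <- lapply(methods_vec(method), function(mth) {
    for (I in candidates) {
      pw <- sw_power(with_n_clusters(design, I), mth)$predicted_power
      if (pw >= target_power) {
        return(tibble::tibble(method = mth, n_clusters = as.integer(I),
                              target_power = target_power, predicted_power = pw))
      }
    }
    stop(sprintf(
      "target power %.3f not reached by n_clusters <= %d (method %s; power at ceiling = %.4f)",
      target_power, max(candidates), mth, pw), call. = FALSE)
  })
  dplyr::bind_rows(rows)
}

#' Minimal detectable HTE odds ratio at a fixed design
#'
#' Bisection for the smallest interaction odds ratio whose predicted power
#' reaches `target_power`, to the stated resolution. The design-stage
#' variance is re-evaluated at each candidate effect size (the marginal means
#' depend on it).
#'
#' @param design An [sw_design()] object (its `theta3` is ignored).
#' @param target_power Target predicted power.
#' @param method `"all"` or subset.
#' @param resolution Reporting resolution on the odds-ratio scale (default
#'   0.01); the returned value is the smallest grid multiple of `resolution`
#'   meeting the target.
#' @param max_or Search ceiling on the odds-ratio scale.
#' @return Tibble with one row per method: `mde_or` and the predicted power
#'   at that odds ratio.
#' @export
sw_find_mde <- function(design, target_power = 0.8, method = "all",
                        resolution = 0.01, max_or = 100) {
  pw_at <- function(orr, mth) {
    d <- with_theta3(design, log(orr))
    sw_power(d, mth)$predicted_power
  }
  rows <- lapply(methods_vec(method), function(mth) {
    lo <- 1; hi <- 2
    while (pw_at(hi, mth) < target_power) {
      lo <- hi; hi <- hi * 2
      if (hi > max_or) {
        stop(sprintf(
          "target power %.3f not reached by odds ratio <= %g (method %s)",
          target_power, max_or, mth), call. = FALSE)
      }
    }
    while (hi - lo > resolution / 4) {
      mid <- (lo + hi) / 2
      if (pw_at(mid, mth) >= target_power) hi <- mid else lo <- mid
    }
    # smallest grid multiple of `resolution` meeting the target
    orr <- max(1, floor(lo / resolution) * resolution)
    while (pw_at(orr, mth) < target_power) {
      orr <- round((orr + resolution) / resolution) * resolution
    }
    tibble::tibble(method = mth, mde_or = orr, target_power = target_power,
                   predicted_power = pw_at(orr, mth))
  })
  dplyr::bind_rows(rows)
}

#' Predicted power over a grid of cluster sizes
#'
#' Convenience sweep used for power curves and for reproducing published
#' power grids: evaluates [sw_power()] at each cluster size.
#'
#' @param design An [sw_design()] object.
#' @param cluster_sizes Integer vector of per-period cluster sizes.
#' @param method `"all"` or subset.
#' @return Tibble of class `sw_power_curve`, one row per (method, size).
#' @export
sw_power_curve <- function(design, cluster_sizes, method = "all") {
  out <- dplyr::bind_rows(lapply(cluster_sizes, function(m) {
    sw_power(with_cluster_size(design, m), method)
  }))
  class(out) <- c("sw_power_curve", class(out))
  out
}

#' Plot a predicted power curve
#'
#' @param object An `sw_power_curve` tibble from [sw_power_curve()].
#' @param ... Unused.
#' @return A ggplot object: predicted power against cluster size, one line
#'   per variance method.
#' @importFrom generics tidy glance
#' @method autoplot sw_power_curve
#' @export
autoplot.sw_power_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$cluster_size, y = .data$predicted_power,
    colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.8, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "cluster size per period (m)", y = "predicted power",
                  colour = "variance") +
    ggplot2::ylim(0, 1)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
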