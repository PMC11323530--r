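#' Specify a cross-sectional stepped-wedge design with an individual binary covariate
#'
#' Bundles every quantity needed for design-stage power calculation of the
#' treatment-by-covariate interaction (heterogeneity of treatment effect, HTE)
#' in a cross-sectional stepped-wedge cluster randomized trial (SW-CRT) with a
#' binary outcome analysed by a marginal logistic model:
#' \deqn{\mathrm{logit}(\mu_{ijk}) = \theta_0 + \gamma_j + \theta_1 W_{ij} +
#'   \theta_2 X_{ijk} + \theta_3 W_{ij} X_{ijk}}
#' where \eqn{W_{ij}} indicates that cluster \eqn{i} is on intervention in
#' period \eqn{j} and \eqn{X_{ijk}} is an individual-level binary covariate
#' (e.g. minority race). \eqn{\theta_1} is the overall treatment effect (OTE),
#' \eqn{\theta_3} the HTE, both on the log odds-ratio scale.
#'
#' The outcome correlation is block exchangeable: two individuals in the same
#' cluster and period are correlated `icc` (the within-period intraclass
#' correlation \eqn{\alpha}), two individuals in the same cluster but
#' different periods are correlated `icc * cac` where `cac` is the cluster
#' autocorrelation \eqn{\rho}. `cac = 1` gives the simple exchangeable
#' structure. Admissibility (positive definiteness of the implied correlation
#' matrix) is checked eagerly here.
#'
#' @param n_clusters Number of clusters \eqn{I}. With the default balanced
#'   schedule it must be divisible by `n_periods - 1`.
#' @param n_periods Number of periods \eqn{J} (at least 2; one baseline period,
#'   all clusters treated in the last period).
#' @param cluster_size Individuals sampled per cluster per period \eqn{m}
#'   (cross-sectional: a fresh sample every period).
#' @param p_covariate Prevalence of the binary covariate within each
#'   cluster-period; `round(cluster_size * p_covariate)` individuals carry
#'   `X = 1` and the count must fall strictly between 0 and `cluster_size`.
#' @param theta0 Baseline log odds of the outcome (control arm, `X = 0`).
#' @param gammas Period fixed effects \eqn{\gamma_1, \dots, \gamma_J} on the
#'   log-odds scale; \eqn{\gamma_1} must be 0 (identification constraint).
#' @param theta1 Overall treatment effect, log odds ratio.
#' @param theta2 Covariate main effect, log odds ratio.
#' @param theta3 Treatment-by-covariate interaction (HTE), log odds ratio;
#'   this is the effect \eqn{\delta} under the alternative.
#' @param icc Within-period intraclass correlation \eqn{\alpha}.
#' @param cac Cluster autocorrelation \eqn{\rho} (ratio of between- to
#'   within-period correlation).
#' @param sig_level Two-sided significance level of the Wald test.
#' @param test `"wald_z"` for the normal-based power formula or `"wald_t"`
#'   for its t-based analogue, recommended with few clusters.
#' @param t_df Degrees of freedom for `test = "wald_t"`; defaults to
#'   `n_clusters - 4` (clusters minus cluster-level parameters).
#' @param schedule Optional `n_clusters x n_periods` 0/1 matrix overriding the
#'   balanced crossover schedule. Rows must be non-decreasing (uni-directional
#'   crossover), the first column all 0 and the last all 1.
#'
#' @return An object of class `sw_design` (a list with the validated fields).
#' @examples
#' d <- sw_design(
#'   n_clusters = 8, n_periods = 5, cluster_size = 20, p_covariate = 0.5,
#'   theta0 = log(0.15 / 0.85), gammas = c(0, 0.1, 0.2, 0.3, 0.4),
#'   theta1 = log(1.68), theta2 = log(1.5), theta3 = log(1.5),
#'   icc = 0.1, cac = 1
#' )
#' sw_power(d)
#' @export
sw_design <- function(n_clusters, n_periods, cluster_size, p_covariate,
                      theta0, gammas, theta1, theta2, theta3,
                      icc, cac = 1, sig_level = 0.05,
                      test = c("wald_z", "wald_t"), t_df = NULL,
                      schedule = NULL) {
  test <- match.arg(test)
  problems <- character()
  note <- function(msg) problems <<- c(problems, msg)

  chk_num <- function(x, nm, len = 1L) {
    if (!is.numeric(x) || length(x) != len || anyNA(x)) {
      note(sprintf("`%s` must be a numeric vector of length %d with no NA", nm, len))
      FALSE
    } else TRUE
  }
  ok_I <- chk_num(n_clusters, "n_clusters") && n_clusters >= 1
  ok_J <- chk_num(n_periods, "n_periods") && n_periods >= 2
  ok_m <- chk_num(cluster_size, "cluster_size") && cluster_size >= 2
  if (!ok_I) note("`n_clusters` must be a positive integer")
  if (!ok_J) note("`n_periods` must be an integer >= 2")
  if (!ok_m) note("`cluster_size` must be an integer >= 2")
  chk_num(theta0, "theta0"); chk_num(theta1, "theta1")
  chk_num(theta2, "theta2"); chk_num(theta3, "theta3")
  if (ok_J) {
    if (!is.numeric(gammas) || length(gammas) != n_periods || anyNA(gammas)) {
      note(sprintf("`gammas` must have length n_periods = %d", n_periods))
    } else if (gammas[1] != 0) {
      note("`gammas[1]` must be 0 (reference period; gamma_1 = 0 for identification)")
    }
  }
  if (chk_num(p_covariate, "p_covariate") &&
      (p_covariate <= 0 || p_covariate >= 1)) {
    note("`p_covariate` must lie strictly in (0, 1)")
  }
  if (ok_m && is.numeric(p_covariate) && length(p_covariate) == 1 &&
      !anyNA(p_covariate)) {
    n1 <- round(cluster_size * p_covariate)
    if (n1 <= 0 || n1 >= cluster_size) {
      note(sprintf(
        "degenerate covariate allocation: round(cluster_size * p_covariate) = %d must be in 1..%d so both covariate levels are present",
        n1, cluster_size - 1))
    }
  }
  if (chk_num(icc, "icc") && (icc <= -1 || icc >= 1)) {
    note("`icc` must lie in (-1, 1)")
  }
  if (chk_num(cac, "cac") && (cac < -1 || cac > 1)) {
    note("`cac` must lie in [-1, 1]")
  }
  if (chk_num(sig_level, "sig_level") && (sig_level <= 0 || sig_level >= 1)) {
    note("`sig_level` must lie strictly in (0, 1)")
  }

  if (is.null(schedule) && ok_I && ok_J &&
      n_clusters %% (n_periods - 1) != 0) {
    note(sprintf(
      "balanced schedule needs n_clusters divisible by n_periods - 1; got n_clusters = %d, n_periods - 1 = %d",
      n_clusters, n_periods - 1))
  }
  if (!is.null(schedule)) {
    if (!is.matrix(schedule) || !all(dim(schedule) == c(n_clusters, n_periods)) ||
        !all(schedule %in% c(0, 1))) {
      note("`schedule` must be an n_clusters x n_periods 0/1 matrix")
    } else {
      if (any(apply(schedule, 1, function(w) any(diff(w) < 0)))) {
        note("`schedule` rows must be non-decreasing (uni-directional crossover)")
      }
      if (any(schedule[, 1] != 0)) note("`schedule` column 1 must be all 0 (baseline period)")
      if (any(schedule[, n_periods] != 1)) note("`schedule` last column must be all 1")
    }
  }

  # eager admissibility of the block-exchangeable correlation
  if (ok_J && ok_m && length(problems) == 0) {
    ev <- nested_exch_eigenvalues(n_periods, cluster_size, icc, cac)
    if (min(ev) <= 0) {
      note(sprintf(
        "inadmissible correlation: eigenvalues of R(alpha = %g, rho = %g) are (%s); all must be > 0",
        icc, cac, paste(signif(ev, 6), collapse = ", ")))
    }
  }

  if (length(problems) > 0) {
    stop("invalid stepped-wedge design:\n", paste0("- ", problems, collapse = "\n"),
         call. = FALSE)
  }

  if (is.null(t_df)) t_df <- max(n_clusters - 4, 1)
  structure(
    list(
      n_clusters = as.integer(n_clusters), n_periods = as.integer(n_periods),
      cluster_size = as.integer(cluster_size), p_covariate = p_covariate,
      theta0 = theta0, gammas = as.numeric(gammas),
      theta1 = theta1, theta2 = theta2, theta3 = theta3,
      icc = icc, cac = cac, sig_level = sig_level,
      test = test, t_df = t_df, schedule = schedule
    ),
    class = "sw_design"
  )
}

#' @export
print.sw_design <- function(x, ...) {
  cat("Cross-sectional stepped-wedge design (binary outcome, HTE analysis)\n")
  cat(sprintf("  clusters I = %d, periods J = %d, cluster size m = %d (per period)\n",
              x$n_clusters, x$n_periods, x$cluster_size))
  cat(sprintf("  covariate prevalence = %.4g (%d of %d per cluster-period)\n",
              x$p_covariate, round(x$cluster_size * x$p_covariate), x$cluster_size))
  cat(sprintf("  theta0 = %.4f, OTE = %.4f, covariate = %.4f, HTE = %.4f (log odds)\n",
              x$theta0, x$theta1, x$theta2, x$theta3))
  cat(sprintf("  gammas = (%s)\n", paste(format(x$gammas), collapse = ", ")))
  cat(sprintf("  ICC alpha = %g, CAC rho = %g; %s test at alpha = %g%s\n",
              x$icc, x$cac, x$test, x$sig_level,
              if (x$test == "wald_t") sprintf(" (df = %d)", x$t_df) else ""))
  invisible(x)
}

#' Treatment schedule and covariate allocation of a stepped-wedge design
#'
#' Expands a design into its layout: the `I x J` treatment indicator matrix
#' `W` (balanced uni-directional crossover unless the design carries a custom
#' schedule), the per cluster-period count of individuals with `X = 1`
#' (deterministic, `round(m * p_covariate)`, placed as the last block of each
#' period — exchangeability within a period makes the ordering irrelevant),
#' and the period-major individual covariate vector.
#'
#' @param design An [sw_design()] object.
#' @return An object of class `sw_layout`: list with `W`, `x_count`,
#'   `covariate` (length `J * m`, period-major), `pattern` (integer vector
#'   mapping each cluster to its crossover pattern) and `start_period` per
#'   pattern (first treated period).
#' @export
sw_layout <- function(design) {
  stopifnot(inherits(design, "sw_design"))
  I <- design$n_clusters; J <- design$n_periods; m <- design$cluster_size
  if (is.null(design$schedule)) {
    per_step <- I / (J - 1)
    start <- rep(2:J, each = per_step)  # first treated period per cluster
    W <- t(vapply(start, function(s) as.numeric(seq_len(J) >= s), numeric(J)))
  } else {
    W <- design$schedule
    start <- apply(W, 1, function(w) if (any(w == 1)) min(which(w == 1)) else J + 1L)
  }
  patt_key <- apply(W, 1, paste, collapse = "")
  pattern <- match(patt_key, unique(patt_key))
  n1 <- round(m * design$p_covariate)
  x <- c(rep(0, m - n1), rep(1, n1))
  structure(
    list(
      W = W,
      x_count = n1,
      covariate = rep(x, times = J),
      pattern = pattern,
      start_period = start[!duplicated(pattern)]
    ),
    class = "sw_layout"
  )
}

#' Marginal outcome probability for a design cell
#'
#' Inverse-logit of \eqn{\theta_0 + \gamma_j + \theta_1 w + \theta_2 x +
#' \theta_3 w x}.
#'
#' @param design An [sw_design()] object.
#' @param period Period index `j` in `1..n_periods`.
#' @param treated Treatment indicator `w` (0 or 1).
#' @param covariate Covariate value `x` (0 or 1).
#' @return Probability strictly in (0, 1). Vectorised over the three indices.
#' @export
sw_marginal_mean <- function(design, period, treated, covariate) {
  stopifnot(inherits(design, "sw_design"))
  if (any(period < 1 | period > design$n_periods)) {
    stop("`period` must lie in 1..", design$n_periods, call. = FALSE)
  }
  stats::plogis(design$theta0 + design$gammas[period] +
                  design$theta1 * treated + design$theta2 * covariate +
                  design$theta3 * treated * covariate)
}

#' Per-cluster design matrices, marginal means and variance diagonals
#'
#' For each distinct crossover pattern, stacks the individual-level rows
#' \eqn{[1, e_j^\top, W_{ij}, X_{ijk}, W_{ij} X_{ijk}]} into the
#' `(J m) x (J + 3)` matrix \eqn{M_i} (period-major), evaluates the marginal
#' means \eqn{u_i} and the Bernoulli variance diagonal
#' \eqn{A_i = u_i (1 - u_i)}. Clusters sharing a pattern share these objects.
#'
#' Columns of \eqn{M_i} are ordered (intercept, period 2..J indicators,
#' W, X, WX), so the parameter vector is
#' \eqn{(\theta_0, \gamma_2, \dots, \gamma_J, \theta_1, \theta_2, \theta_3)}
#' and the HTE coefficient is always the last (position `J + 3`), with the
#' OTE at position `J + 1`.
#'
#' @param design An [sw_design()] object.
#' @param layout Optional precomputed [sw_layout()].
#' @return List with `patterns` (per pattern: `M`, `mu`, `A`, `n_clusters`),
#'   `cluster_pattern`, `theta` (the coefficient vector in column order) and
#'   index positions `idx_hte`, `idx_ote`.
#' @export
sw_design_matrices <- function(design, layout = sw_layout(design)) {
  J <- design$n_periods; m <- design$cluster_size
  theta <- c(design$theta0, design$gammas[-1], design$theta1, design$theta2,
             design$theta3)
  x <- layout$covariate[seq_len(m)]
  pats <- lapply(seq_along(layout$start_period), function(p) {
    wrow <- layout$W[match(p, layout$pattern), ]
    rows <- lapply(seq_len(J), function(j) {
      ej <- matrix(0, m, J - 1)
      if (j >= 2) ej[, j - 1] <- 1
      cbind(1, ej, wrow[j], x, wrow[j] * x, deparse.level = 0)
    })
    M <- do.call(rbind, rows)
    colnames(M) <- c("(Intercept)", paste0("period", 2:J), "W", "X", "W:X")
    mu <- stats::plogis(drop(M %*% theta))
    list(M = M, mu = mu, A = mu * (1 - mu),
         n_clusters = sum(layout$pattern == p))
  })
  list(patterns = pats, cluster_pattern = layout$pattern, theta = theta,
       idx_hte = J + 3L, idx_ote = J + 1L)
}
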