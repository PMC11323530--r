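#' Latent Gaussian correlation solving the bivariate copula equation
#'
#' For two binary variables with means `mu1`, `mu2` and target Pearson
#' correlation `target_corr`, finds the latent normal correlation \eqn{\xi}
#' such that thresholding a standard bivariate normal at
#' \eqn{\Phi^{-1}(\mu_1), \Phi^{-1}(\mu_2)} reproduces the target joint
#' success probability
#' \eqn{P(Y_1 = 1, Y_2 = 1) = \mu_1\mu_2 + r\sqrt{v_1 v_2}}:
#' \deqn{\Phi_2(\Phi^{-1}(\mu_1), \Phi^{-1}(\mu_2); \xi) = P(Y_1=1, Y_2=1).}
#' The joint probability must respect the Frechet-Hoeffding bounds
#' \eqn{[\max(0, \mu_1 + \mu_2 - 1), \min(\mu_1, \mu_2)]}.
#'
#' @param mu1,mu2 Marginal success probabilities, strictly in (0, 1).
#' @param target_corr Target Pearson correlation of the binary pair.
#' @param tol Tolerance on the joint probability for the bracketed root
#'   search over \eqn{\xi \in [-0.9999, 0.9999]}.
#' @return The latent correlation \eqn{\xi} in (-1, 1).
#' @export
copula_latent_corr <- function(mu1, mu2, target_corr, tol = 1e-8) {
  stopifnot(mu1 > 0, mu1 < 1, mu2 > 0, mu2 < 1)
  if (target_corr == 0) return(0)
  p11 <- target_corr * sqrt(mu1 * (1 - mu1) * mu2 * (1 - mu2)) + mu1 * mu2
  lo_b <- max(0, mu1 + mu2 - 1); hi_b <- min(mu1, mu2)
  if (p11 < lo_b - 1e-12 || p11 > hi_b + 1e-12) {
    stop(sprintf(
      "infeasible correlation %g for margins (%g, %g): joint probability %g outside Frechet bounds [%g, %g]",
      target_corr, mu1, mu2, p11, lo_b, hi_b), call. = FALSE)
  }
  q1 <- stats::qnorm(mu1); q2 <- stats::qnorm(mu2)
  f <- function(xi) pbinorm(q1, q2, xi) - p11
  stats::uniroot(f, c(-0.9999, 0.9999), tol = tol, extendInt = "no")$root
}

# bivariate standard normal CDF with correlation xi
pbinorm <- function(q1, q2, xi) {
  mvtnorm::pmvnorm(upper = c(q1, q2),
                   corr = matrix(c(1, xi, xi, 1), 2, 2))[1]
}

#' Eigenvalue repair of a symmetric matrix to positive semidefiniteness
#'
#' Eigenvalues below `floor` are raised to `floor`, the matrix is
#' reconstructed and rescaled back to unit diagonal. Used when the pairwise
#' latent correlation matrix assembled by the copula construction is not
#' positive semidefinite.
#'
#' @param mat Symmetric matrix with unit diagonal.
#' @param floor Minimum retained eigenvalue.
#' @return List with `mat` (repaired, unit diagonal), `repaired` (logical),
#'   and `max_change` (largest absolute entry change).
#' @export
repair_psd <- function(mat, floor = 1e-6) {
  es <- eigen(mat, symmetric = TRUE)
  if (min(es$values) >= floor) {
    return(list(mat = mat, repaired = FALSE, max_change = 0))
  }
  vals <- pmax(es$values, floor)
  out <- es$vectors %*% (vals * t(es$vectors))
  d <- sqrt(diag(out))
  out <- out / (d %o% d)
  list(mat = out, repaired = TRUE, max_change = max(abs(out - mat)))
}

#' Per-pattern latent Gaussian correlation matrices for outcome simulation
#'
#' Assembles, for each crossover pattern of the design, the `Jm x Jm` latent
#' correlation matrix whose thresholded multivariate normal reproduces the
#' design's marginal means and block-exchangeable outcome correlation
#' (within-period `icc`, cross-period `icc * cac`). Only the distinct
#' (mean, mean, within/between) combinations are solved (cached), the matrix
#' is eigenvalue-repaired if needed, and its lower Cholesky factor is stored
#' for sampling.
#'
#' @param design An [sw_design()] object.
#' @param eigen_floor Floor for [repair_psd()].
#' @return Object of class `sw_latent`: per pattern a list with `factor`
#'   (lower-triangular), `thresholds` (`qnorm` of the marginal means),
#'   `repaired`, `max_change`; plus the cluster-to-pattern map and the count
#'   of distinct pairwise equations solved (`n_xi_solved`).
#' @export
sw_latent <- function(design, eigen_floor = 1e-6) {
  dm <- sw_design_matrices(design)
  J <- design$n_periods; m <- design$cluster_size
  alpha <- design$icc; rho <- design$cac
  cache <- new.env(parent = emptyenv())
  xi_cached <- function(mu_a, mu_b, target) {
    if (target == 0) return(0)
    mus <- sort(c(mu_a, mu_b))
    key <- sprintf("%.15g|%.15g|%.15g", mus[1], mus[2], target)
    if (is.null(cache[[key]])) cache[[key]] <- copula_latent_corr(mus[1], mus[2], target)
    cache[[key]]
  }
  per <- rep(seq_len(J), each = m)
  patterns <- lapply(dm$patterns, function(pat) {
    # distinct rows: class = (period, covariate); means constant within class
    x <- as.integer(pat$M[seq_len(m), J + 2])  # covariate block of one period
    cls <- (per - 1L) * 2L + rep(x, J) + 1L
    mu_cls <- vapply(seq_len(2L * J), function(cc) {
      idx <- which(cls == cc)[1]
      pat$mu[idx]
    }, numeric(1))
    ncls <- 2L * J
    cls_per <- rep(seq_len(J), each = 2)
    Lw <- Lb <- matrix(NA_real_, ncls, ncls)
    for (a in seq_len(ncls)) for (b in seq_len(a)) {
      Lw[a, b] <- Lw[b, a] <- xi_cached(mu_cls[a], mu_cls[b], alpha)
      Lb[a, b] <- Lb[b, a] <- xi_cached(mu_cls[a], mu_cls[b], alpha * rho)
    }
    same <- outer(cls_per[cls], cls_per[cls], "==")
    Xi <- ifelse(same, Lw[cls, cls], Lb[cls, cls])
    diag(Xi) <- 1
    rep_out <- repair_psd(Xi, eigen_floor)
    if (rep_out$repaired) {
      message(sprintf(
        "latent correlation repaired: eigenvalues floored at %g (max entry change %.3g)",
        eigen_floor, rep_out$max_change))
    }
    list(factor = t(chol(rep_out$mat + diag(1e-12, nrow(Xi)))),
         thresholds = stats::qnorm(pat$mu),
         mu = pat$mu,
         repaired = rep_out$repaired, max_change = rep_out$max_change,
         n_clusters = pat$n_clusters)
  })
  structure(list(patterns = patterns, cluster_pattern = dm$cluster_pattern,
                 n_xi_solved = length(ls(cache))),
            class = "sw_latent")
}

#' Simulate correlated binary outcomes from a stepped-wedge design
#'
#' Draws, for each replicate, one latent normal vector per cluster from the
#' pattern's factorised latent correlation and thresholds it at
#' \eqn{\Phi^{-1}(\mu_{ijk})}, yielding binary outcomes with the design's
#' marginal means and intracluster correlation. Deterministic given the seed.
#'
#' @param design An [sw_design()] object (its coefficients are the
#'   data-generating values).
#' @param n_reps Number of replicate datasets.
#' @param seed Integer seed (set once before sequential sampling).
#' @param latent Optional precomputed [sw_latent()] for this design.
#' @return Tibble with columns `replicate`, `cluster`, `period`,
#'   `individual`, `W`, `X`, `Y` (period-major within cluster).
#' @export
sw_simulate <- function(design, n_reps = 1, seed = NULL, latent = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(latent)) latent <- sw_latent(design)
  layout <- sw_layout(design)
  J <- design$n_periods; m <- design$cluster_size; n <- J * m
  I <- design$n_clusters
  base <- tibble::tibble(
    cluster = rep(seq_len(I), each = n),
    period = rep(rep(seq_len(J), each = m), times = I),
    individual = rep(rep(seq_len(m), times = J), times = I),
    W = rep(as.vector(t(layout$W)), each = m),
    X = rep(layout$covariate, times = I)
  )
  reps <- lapply(seq_len(n_reps), function(r) {
    Y <- numeric(I * n)
    for (i in seq_len(I)) {
      pat <- latent$patterns[[latent$cluster_pattern[i]]]
      z <- drop(pat$factor %*% stats::rnorm(n))
      Y[(i - 1L) * n + seq_len(n)] <- as.numeric(z <= pat$thresholds)
    }
    dplyr::mutate(base, replicate = r, Y = Y, .before = 1)
  })
  dplyr::bind_rows(reps)
}
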