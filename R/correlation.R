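#' Block-exchangeable (nested exchangeable) outcome correlation structure
#'
#' The correlation matrix of the `J * m` binary outcomes of one cluster is
#' \deqn{R(\alpha, \rho) = \alpha\rho J_{Jm} + \alpha(1 - \rho) I_J \otimes J_m
#'   + (1 - \alpha) I_{Jm}}
#' with unit diagonal, within-period off-diagonal entries \eqn{\alpha} (the
#' ICC) and cross-period entries \eqn{\alpha\rho} (ICC times the cluster
#' autocorrelation). It has exactly three distinct eigenvalues,
#' \deqn{\lambda_1 = 1 - \alpha, \quad
#'   \lambda_2 = 1 - \alpha + m\alpha(1 - \rho), \quad
#'   \lambda_3 = 1 - \alpha + m\alpha(1 - \rho) + Jm\alpha\rho,}
#' on the orthogonal eigenspaces (within-period contrasts, between-period
#' contrasts of period means, the overall mean), which gives a closed-form
#' inverse used throughout the variance engine.
#'
#' @name sw_correlation
NULL

# eigenvalues of R(alpha, rho) for a J x m block-exchangeable structure
nested_exch_eigenvalues <- function(J, m, alpha, rho) {
  c(within = 1 - alpha,
    between = 1 - alpha + m * alpha * (1 - rho),
    grand = 1 - alpha + m * alpha * (1 - rho) + J * m * alpha * rho)
}

#' Build a correlation bundle for one cluster
#'
#' @param J Number of periods.
#' @param m Cluster size per period.
#' @param alpha Within-period intraclass correlation (ICC).
#' @param rho Cluster autocorrelation (CAC); `rho = 1` collapses the nested
#'   structure to simple exchangeable.
#' @return Object of class `sw_corr` holding the dimensions, the three
#'   eigenvalues, and the parameters. Dense forms are materialised on demand
#'   by [corr_matrix()] / [corr_inverse()]; structured products (never
#'   forming the `Jm x Jm` matrix) by [corr_inv_mult()].
#' @export
sw_correlation <- function(J, m, alpha, rho = 1) {
  ev <- nested_exch_eigenvalues(J, m, alpha, rho)
  if (min(ev) <= 0) {
    bad <- names(ev)[which.min(ev)]
    stop(sprintf(
      "R(alpha = %g, rho = %g) with J = %d, m = %d is not positive definite: %s-block eigenvalue = %g <= 0",
      alpha, rho, J, m, bad, min(ev)), call. = FALSE)
  }
  structure(list(J = J, m = m, alpha = alpha, rho = rho, eigenvalues = ev),
            class = "sw_corr")
}

#' @rdname sw_correlation
#' @param bundle An `sw_corr` object.
#' @return `corr_matrix()`: the dense `Jm x Jm` correlation matrix.
#' @export
corr_matrix <- function(bundle) {
  with(bundle, {
    n <- J * m
    R <- matrix(alpha * rho, n, n)
    per <- rep(seq_len(J), each = m)
    same <- outer(per, per, "==")
    R[same] <- alpha
    diag(R) <- 1
    R
  })
}

#' @rdname sw_correlation
#' @return `corr_inverse()`: the dense closed-form inverse of `R`, built from
#'   the three-eigenvalue spectral decomposition.
#' @export
corr_inverse <- function(bundle) {
  # R^{-1} = 1/l1 (I - P) + 1/l2 (P - G) + 1/l3 G, with
  # P = I_J (x) J_m / m (period-mean projector) and G = J_n / n
  J <- bundle$J; m <- bundle$m; n <- J * m
  l <- bundle$eigenvalues
  per <- rep(seq_len(J), each = m)
  P <- matrix(0, n, n); P[outer(per, per, "==")] <- 1 / m
  G <- matrix(1 / n, n, n)
  (diag(n) - P) / l[1] + (P - G) / l[2] + G / l[3]
}

#' Multiply the inverse correlation matrix onto a vector or matrix
#'
#' Computes `R^{-1} %*% y` in `O(n)` per column using the spectral form,
#' without materialising `R`. Rows of `y` must be period-major (all
#' individuals of period 1, then period 2, ...).
#'
#' @param bundle An `sw_corr` object.
#' @param y Numeric vector of length `J * m` or matrix with that many rows.
#' @return Same shape as `y`.
#' @export
corr_inv_mult <- function(bundle, y) {
  J <- bundle$J; m <- bundle$m; n <- J * m
  l <- bundle$eigenvalues
  y <- as.matrix(y)
  stopifnot(nrow(y) == n)
  # period means, replicated back to full length
  dim(y) <- c(m, J * ncol(y))
  pm <- colMeans(y)                      # per (period, column)
  Pm <- matrix(rep(pm, each = m), nrow = m)
  dim(y) <- c(n, length(pm) / J)
  dim(Pm) <- dim(y)
  Gm <- matrix(rep(colMeans(y), each = n), nrow = n)
  (y - Pm) / l[1] + (Pm - Gm) / l[2] + Gm / l[3]
}
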