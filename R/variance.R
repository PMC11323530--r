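#' Design-stage variance of the GEE estimator, with bias-corrected sandwich forms
#'
#' Approximates \eqn{\mathrm{Var}(\hat\Theta)} for the marginal logistic model
#' of an [sw_design()] at the assumed parameter and correlation values:
#'
#' * `"GEE"` — the model-based (naive) form
#'   \eqn{(\sum_i M_i^\top \Sigma_i^{-1} M_i)^{-1}} with
#'   \eqn{\Sigma_i = A_i^{-1/2} R_i A_i^{-1/2}};
#' * `"GEE-KC"` — Kauermann-Carroll corrected sandwich, residual modification
#'   \eqn{F_i = (I - H_i)^{-1/2}} (principal matrix square root);
#' * `"GEE-MD"` — Mancl-DeRouen corrected sandwich,
#'   \eqn{F_i = (I - H_i)^{-1}};
#'
#' where \eqn{H_i = A_i M_i (\sum_i M_i^\top \Sigma_i^{-1} M_i)^{-1}
#' M_i^\top \Sigma_i^{-1} A_i^{-1}} is the cluster leverage and the corrected
#' covariance is the three-factor sandwich with middle term
#' \eqn{\sum_i M_i^\top \Omega_i^{-1} M_i},
#' \eqn{\Omega_i^{-1} = \Sigma_i^{-1} A_i^{-1} F_i A_i \Sigma_i A_i F_i^\top
#' A_i^{-1} \Sigma_i^{-1}}. With \eqn{F_i = I} the sandwich collapses exactly
#' to the model-based form.
#'
#' @details
#' The default engine never forms a `Jm x Jm` matrix: because
#' \eqn{H_i = U_i C_i^\top} has rank at most `J + 3`
#' (\eqn{U_i = A_i M_i}, \eqn{C_i^\top = B^{-1} M_i^\top \Sigma_i^{-1}
#' A_i^{-1}}, \eqn{B} the total information), any analytic function
#' \eqn{f(I - H_i)} equals \eqn{I + U_i \phi(S_i) C_i^\top} with
#' \eqn{S_i = C_i^\top U_i = B^{-1} B_i} and
#' \eqn{\phi(x) = (f(1 - x) - 1)/x}, and the whole middle term reduces to
#' products of the `(J+3) x (J+3)` per-pattern information blocks
#' \eqn{B_i = M_i^\top \Sigma_i^{-1} M_i}:
#' \deqn{M_i^\top \Omega_i^{-1} M_i = B_i + B_i B^{-1} \phi(S_i)^\top B_i +
#'   B_i \phi(S_i) B^{-1} B_i + B_i \phi(S_i) B^{-1} B_i B^{-1}
#'   \phi(S_i)^\top B_i.}
#' \eqn{S_i} is similar to a symmetric PSD matrix, so its eigenvalues are
#' real; admissible designs have them strictly below 1, which makes the
#' principal square root well defined. `engine = "dense"` is a literal dense
#' transcription of the displayed formulas (including the explicit
#' non-symmetric principal square root of \eqn{I - H_i}) kept as an oracle;
#' the two agree to numerical precision.
#'
#' @param design An [sw_design()] object.
#' @param method One of `"GEE"`, `"GEE-KC"`, `"GEE-MD"` (case-insensitive;
#'   `"kc"`, `"md"`, `"gee"` accepted).
#' @param engine `"pattern"` (fast exact reduction, default) or `"dense"`.
#' @return Object of class `sw_variance`: list with `method`, `full_cov`
#'   (`(J+3) x (J+3)`), `var_hte`, `var_ote`, and the column order of the
#'   parameter vector.
#' @export
sw_variance <- function(design, method = c("GEE", "GEE-KC", "GEE-MD"),
                        engine = c("pattern", "dense")) {
  method <- normalize_method(method[1])
  engine <- match.arg(engine)
  dm <- sw_design_matrices(design)
  cov <- if (engine == "pattern") {
    variance_pattern(design, dm, method)
  } else {
    variance_dense(design, dm, method)
  }
  new_sw_variance(cov, method, dm)
}

new_sw_variance <- function(cov, method, dm) {
  cov <- (cov + t(cov)) / 2
  structure(
    list(method = method, full_cov = cov,
         var_hte = cov[dm$idx_hte, dm$idx_hte],
         var_ote = cov[dm$idx_ote, dm$idx_ote],
         terms = colnames(dm$patterns[[1]]$M)),
    class = "sw_variance"
  )
}

normalize_method <- function(method) {
  key <- gsub("^GEE-?", "", toupper(method))
  if (key == "") return("GEE")
  switch(key, "KC" = "GEE-KC", "MD" = "GEE-MD",
         stop("unknown method: ", method, call. = FALSE))
}

#' @export
print.sw_variance <- function(x, ...) {
  cat(sprintf("%s design-stage covariance (%d parameters)\n",
              x$method, ncol(x$full_cov)))
  cat(sprintf("  Var(HTE) = %.6g  SE = %.6g\n", x$var_hte, sqrt(x$var_hte)))
  cat(sprintf("  Var(OTE) = %.6g  SE = %.6g\n", x$var_ote, sqrt(x$var_ote)))
  invisible(x)
}

# per-pattern information blocks B_i = M' Sigma^{-1} M (one per crossover
# pattern) plus the total information B, via the structured R^{-1}
pattern_information <- function(design, dm) {
  J <- design$n_periods; m <- design$cluster_size
  bundle <- sw_correlation(J, m, design$icc, design$cac)
  Bs <- lapply(dm$patterns, function(p) {
    Tm <- sqrt(p$A) * p$M                 # A^{1/2} M
    crossprod(Tm, corr_inv_mult(bundle, Tm))
  })
  B <- Reduce(`+`, Map(function(b, p) p$n_clusters * b, Bs, dm$patterns))
  list(Bs = Bs, B = B)
}

phi_correction <- function(method) {
  switch(method,
    "GEE" = function(x) rep(0, length(x)),
    "GEE-KC" = function(x) ifelse(abs(x) < 1e-9, 0.5 + 0.375 * x,
                                  ((1 - x)^(-0.5) - 1) / x),
    "GEE-MD" = function(x) 1 / (1 - x)
  )
}

variance_pattern <- function(design, dm, method) {
  info <- pattern_information(design, dm)
  B <- info$B
  Binv <- chol2inv(chol(B))
  if (method == "GEE") return(Binv)
  phi <- phi_correction(method)
  q <- ncol(B)
  meat <- matrix(0, q, q)
  for (k in seq_along(info$Bs)) {
    Bi <- info$Bs[[k]]
    S <- Binv %*% Bi
    es <- eigen(S)
    if (max(Re(es$values)) >= 1) {
      stop(sprintf(
        "bias correction failed: leverage eigenvalue %.4g >= 1 for pattern %d; the cluster carries too much of the total information (increase n_clusters or cluster_size)",
        max(Re(es$values)), k), call. = FALSE)
    }
    PhiS <- Re(es$vectors %*% (phi(es$values) * solve(es$vectors)))
    BPhi <- Bi %*% PhiS
    term <- Bi + t(BPhi %*% Binv %*% Bi) + BPhi %*% Binv %*% Bi +
      BPhi %*% Binv %*% Bi %*% Binv %*% t(BPhi)
    meat <- meat + dm$patterns[[k]]$n_clusters * term
  }
  Binv %*% meat %*% Binv
}

# literal dense transcription of the displayed variance formulas; oracle path
variance_dense <- function(design, dm, method) {
  J <- design$n_periods; m <- design$cluster_size
  bundle <- sw_correlation(J, m, design$icc, design$cac)
  R <- corr_matrix(bundle)
  Rinv <- solve(R)
  clusters <- lapply(dm$cluster_pattern, function(p) dm$patterns[[p]])
  n <- J * m
  pieces <- lapply(clusters, function(cl) {
    Ah <- sqrt(cl$A)
    Sigma_inv <- (Ah %o% Ah) * Rinv            # A^{1/2} R^{-1} A^{1/2}
    Sigma <- outer(1 / Ah, 1 / Ah) * R          # A^{-1/2} R A^{-1/2}
    list(M = cl$M, A = cl$A, Sigma = Sigma, Sigma_inv = Sigma_inv)
  })
  B <- Reduce(`+`, lapply(pieces, function(p) t(p$M) %*% p$Sigma_inv %*% p$M))
  Binv <- solve(B)
  if (method == "GEE") return(Binv)
  meat <- 0
  for (p in pieces) {
    H <- diag(p$A) %*% p$M %*% Binv %*% t(p$M) %*% p$Sigma_inv %*% diag(1 / p$A)
    IH <- diag(n) - H
    Fi <- if (method == "GEE-MD") solve(IH) else dense_principal_inv_sqrt(IH)
    Omega_inv <- p$Sigma_inv %*% diag(1 / p$A) %*% Fi %*% diag(p$A) %*%
      p$Sigma %*% diag(p$A) %*% t(Fi) %*% diag(1 / p$A) %*% p$Sigma_inv
    meat <- meat + t(p$M) %*% Omega_inv %*% p$M
  }
  Binv %*% meat %*% Binv
}

# principal (I - H)^{-1/2} of a (generally non-symmetric) matrix via
# eigendecomposition; imaginary residue checked and discarded
dense_principal_inv_sqrt <- function(X, tol = 1e-8) {
  es <- eigen(X)
  if (any(Re(es$values) <= 0)) {
    stop("matrix has non-positive eigenvalues; principal inverse square root undefined",
         call. = FALSE)
  }
  out <- es$vectors %*% (es$values^(-0.5) * solve(es$vectors))
  if (max(abs(Im(out))) > tol) {
    stop("principal square root has non-negligible imaginary part", call. = FALSE)
  }
  Re(out)
}
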