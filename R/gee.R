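#' Fit the marginal logistic model by GEE with an exchangeable-family working correlation
#'
#' Fisher-scoring solution of the generalized estimating equations
#' \eqn{\sum_i M_i^\top A_i V_i^{-1} (Y_i - u_i) = 0} for the stepped-wedge
#' marginal logistic model, alternating coefficient updates with moment
#' re-estimation of the working correlation parameters from standardized
#' Pearson-residual cross-products: within-period pair products estimate the
#' ICC \eqn{\hat\alpha}, cross-period pair products estimate
#' \eqn{\hat\alpha\hat\rho}.
#'
#' @param data Data frame with columns `cluster`, `period`, `W`, `X`, `Y`
#'   (one row per individual), e.g. one replicate from [sw_simulate()].
#' @param working Working correlation: `"nested"` (exchangeable within and
#'   between periods, both `alpha` and `rho` estimated), `"exchangeable"`
#'   (simple exchangeable, `rho` fixed at 1, a single pooled `alpha`), or
#'   `"independence"` (`alpha = rho = 0` fixed; coincides with ordinary
#'   logistic maximum likelihood).
#' @param model `"hte"` fits the full model (periods, treatment, covariate,
#'   interaction); `"ote"` fits the reduced model without covariate terms
#'   (periods and treatment only), targeting the overall treatment effect.
#' @param alpha_init,rho_init Starting values for the correlation moments.
#' @param tol Convergence tolerance on the maximum absolute parameter change.
#' @param max_iter Iteration cap; hitting it flags the fit as non-converged
#'   rather than raising an error.
#' @return Object of class `sw_gee`: coefficient estimates `theta`
#'   (interaction last), `alpha_hat`, `rho_hat`, covariance matrices
#'   `naive_cov`, `robust_cov`, `kc_cov`, `md_cov`, convergence flags and
#'   iteration count. Non-convergence and separation are flagged, not thrown.
#' @export
sw_gee <- function(data, working = c("nested", "exchangeable", "independence"),
                   model = c("hte", "ote"),
                   alpha_init = 0.05, rho_init = 0.8,
                   tol = 1e-6, max_iter = 100) {
  working <- match.arg(working)
  model <- match.arg(model)
  stopifnot(all(c("cluster", "period", "W", "X", "Y") %in% names(data)))
  if (length(unique(data$Y)) < 2) {
    stop("both outcome values must be present", call. = FALSE)
  }
  periods <- sort(unique(data$period))
  J <- length(periods)
  clusters <- unique(data$cluster)
  ord <- order(match(data$cluster, clusters), match(data$period, periods))
  data <- data[ord, ]
  m <- nrow(data) / (length(clusters) * J)
  stopifnot(m == round(m))  # equal cluster-period sizes assumed

  P <- matrix(0, nrow(data), J - 1)
  for (j in 2:J) P[data$period == periods[j], j - 1] <- 1
  Mfull <- cbind(1, P, data$W, data$X, data$W * data$X, deparse.level = 0)
  colnames(Mfull) <- c("(Intercept)", paste0("period", 2:J), "W", "X", "W:X")
  M <- if (model == "hte") Mfull else Mfull[, seq_len(J + 1), drop = FALSE]
  q <- ncol(M)
  y <- data$Y
  ncl <- length(clusters)
  n <- J * m
  idx <- split(seq_len(nrow(data)), rep(seq_len(ncl), each = n))

  # initial coefficients from pooled logistic regression
  theta <- tryCatch(
    stats::glm.fit(M, y, family = stats::binomial())$coefficients,
    error = function(e) rep(0, q))
  if (anyNA(theta)) theta <- rep(0, q)
  alpha <- if (working == "independence") 0 else alpha_init
  rho <- switch(working, nested = rho_init, exchangeable = 1, independence = 0)

  moments <- function(r) {
    # r: n x ncl matrix of Pearson residuals, period-major rows
    dim(r) <- c(m, J * ncl)
    s <- colSums(r); ssq <- colSums(r^2)
    within <- sum(s^2 - ssq) / 2
    S <- colSums(matrix(s, J, ncl))         # per-cluster totals
    between <- sum(S^2 - colSums(matrix(s^2, J, ncl))) / 2
    nw <- ncl * J * m * (m - 1) / 2
    nb <- ncl * J * (J - 1) / 2 * m^2
    c(within = within / nw, between = between / nb)
  }

  converged <- FALSE; flagged <- ""
  iter <- 0
  for (iter in seq_len(max_iter)) {
    eta <- drop(M %*% theta)
    mu <- stats::plogis(eta)
    if (any(mu < 1e-10) || any(mu > 1 - 1e-10) || max(abs(theta)) > 30) {
      flagged <- "separation"
      break
    }
    A <- mu * (1 - mu)
    bundle <- sw_correlation(J, m, alpha, rho)
    Tm <- sqrt(A) * M
    r <- (y - mu) / sqrt(A)
    B <- matrix(0, q, q); score <- numeric(q)
    for (ix in idx) {
      RiT <- corr_inv_mult(bundle, Tm[ix, , drop = FALSE])
      B <- B + crossprod(Tm[ix, , drop = FALSE], RiT)
      score <- score + drop(crossprod(RiT, r[ix]))
    }
    step <- solve(B, score)
    theta_new <- theta + step
    # correlation moments from residuals at the updated mean
    if (working != "independence") {
      mu2 <- stats::plogis(drop(M %*% theta_new))
      r2 <- matrix((y - mu2) / sqrt(mu2 * (1 - mu2)), nrow = n)
      mm <- moments(r2)
      if (working == "nested") {
        alpha_new <- min(max(mm[["within"]], 0), 0.95)
        rho_new <- if (alpha_new > 1e-8) {
          min(max(mm[["between"]] / alpha_new, 0), 1)
        } else 0
      } else {
        nw <- J * m * (m - 1) / 2; nb <- J * (J - 1) / 2 * m^2
        alpha_new <- min(max((mm[["within"]] * nw + mm[["between"]] * nb) /
                               (nw + nb), 0), 0.95)
        rho_new <- 1
      }
    } else {
      alpha_new <- 0; rho_new <- 0
    }
    delta <- max(abs(theta_new - theta), abs(alpha_new - alpha),
                 abs(rho_new - rho))
    theta <- theta_new; alpha <- alpha_new; rho <- rho_new
    if (delta < tol) { converged <- TRUE; break }
  }

  # covariance estimators at the final parameters
  eta <- drop(M %*% theta); mu <- stats::plogis(eta)
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  A <- mu * (1 - mu)
  bundle <- sw_correlation(J, m, alpha, rho)
  Tm <- sqrt(A) * M
  r <- (y - mu) / sqrt(A)
  B <- matrix(0, q, q)
  ks <- vector("list", ncl); Bis <- vector("list", ncl)
  for (i in seq_len(ncl)) {
    ix <- idx[[i]]
    RiT <- corr_inv_mult(bundle, Tm[ix, , drop = FALSE])
    Bis[[i]] <- crossprod(Tm[ix, , drop = FALSE], RiT)
    ks[[i]] <- drop(crossprod(RiT, r[ix]))   # M' A V^{-1} (y - mu)
    B <- B + Bis[[i]]
  }
  naive <- tryCatch(solve(B), error = function(e) matrix(NA_real_, q, q))
  sandwich_cov <- function(method) {
    phi <- phi_correction(method)
    meat <- matrix(0, q, q)
    for (i in seq_len(ncl)) {
      g <- ks[[i]]
      if (method != "GEE") {
        S <- naive %*% Bis[[i]]
        es <- eigen(S)
        if (max(Re(es$values)) >= 1) return(matrix(NA_real_, q, q))
        PhiS <- Re(es$vectors %*% (phi(es$values) * solve(es$vectors)))
        g <- g + Bis[[i]] %*% PhiS %*% naive %*% g
      }
      meat <- meat + g %*% t(g)
    }
    naive %*% meat %*% naive
  }
  score_final <- Reduce(`+`, ks)
  structure(
    list(model = model, working = working,
         theta = stats::setNames(theta, colnames(M)),
         alpha_hat = alpha, rho_hat = rho,
         naive_cov = naive,
         robust_cov = sandwich_cov("GEE"),
         kc_cov = sandwich_cov("GEE-KC"),
         md_cov = sandwich_cov("GEE-MD"),
         converged = converged && flagged == "",
         flag = flagged, n_iter = iter,
         max_score = max(abs(score_final)),
         n_clusters = ncl, n_periods = J, cluster_size = m,
         idx_target = if (model == "hte") q else q),
    class = "sw_gee"
  )
}

#' @export
print.sw_gee <- function(x, ...) {
  cat(sprintf("GEE fit (%s model, %s working correlation): %s after %d iterations\n",
              x$model, x$working,
              if (x$converged) "converged" else paste("NOT converged", x$flag),
              x$n_iter))
  print(round(x$theta, 4))
  cat(sprintf("  alpha_hat = %.4f, rho_hat = %.4f\n", x$alpha_hat, x$rho_hat))
  invisible(x)
}

#' Tidy method for GEE fits
#'
#' @param x An `sw_gee` object.
#' @param se Which standard error to report: `"naive"`, `"robust"`, `"kc"`
#'   or `"md"`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value` (normal reference).
#' @method tidy sw_gee
#' @export
tidy.sw_gee <- function(x, se = c("naive", "robust", "kc", "md"), ...) {
  se <- match.arg(se)
  V <- switch(se, naive = x$naive_cov, robust = x$robust_cov,
              kc = x$kc_cov, md = x$md_cov)
  s <- sqrt(diag(V))
  z <- x$theta / s
  tibble::tibble(term = names(x$theta), estimate = unname(x$theta),
                 std.error = s, statistic = unname(z),
                 p.value = 2 * stats::pnorm(-abs(unname(z))))
}

#' Glance method for GEE fits
#'
#' @param x An `sw_gee` object.
#' @param ... Unused.
#' @return One-row tibble with fit-level summaries.
#' @method glance sw_gee
#' @export
glance.sw_gee <- function(x, ...) {
  tibble::tibble(
    model = x$model, working = x$working,
    alpha_hat = x$alpha_hat, rho_hat = x$rho_hat,
    converged = x$converged, n_iter = x$n_iter, max_score = x$max_score,
    n_clusters = x$n_clusters, n_periods = x$n_periods,
    cluster_size = x$cluster_size
  )
}

#' @export
generics::tidy

#' @export
generics::glance

#' Wald test for the target effect of a GEE fit
#'
#' Tests the interaction coefficient (HTE model) or the treatment coefficient
#' (OTE model) against zero with the chosen standard-error estimator.
#'
#' @param fit An `sw_gee` object.
#' @param se `"naive"`, `"robust"`, `"kc"` or `"md"`.
#' @param sig_level Two-sided level.
#' @param test `"wald_z"` or `"wald_t"`.
#' @param df Degrees of freedom for the t reference; default
#'   `n_clusters - 4`.
#' @return One-row tibble: `estimate`, `std.error`, `statistic`, `reject`.
#' @export
sw_gee_test <- function(fit, se = c("naive", "robust", "kc", "md"),
                        sig_level = 0.05, test = c("wald_z", "wald_t"),
                        df = NULL) {
  se <- match.arg(se); test <- match.arg(test)
  V <- switch(se, naive = fit$naive_cov, robust = fit$robust_cov,
              kc = fit$kc_cov, md = fit$md_cov)
  k <- length(fit$theta)
  est <- unname(fit$theta[k])
  sd_ <- sqrt(V[k, k])
  stat <- est / sd_
  crit <- if (test == "wald_z") stats::qnorm(1 - sig_level / 2) else {
    if (is.null(df)) df <- max(fit$n_clusters - 4, 1)
    stats::qt(1 - sig_level / 2, df)
  }
  tibble::tibble(term = names(fit$theta)[k], estimate = est, std.error = sd_,
                 statistic = stat, reject = is.finite(stat) && abs(stat) > crit)
}
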