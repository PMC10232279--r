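#' Variational Bayesian Gaussian mixture model
#'
#' Fits a finite Gaussian mixture with `K_max` components by mean-field
#' variational inference under a Dirichlet prior on the mixing weights and
#' Gaussian-Wishart priors on the component parameters.  A small Dirichlet
#' concentration (`alpha0 = 1/K_max` by default) drives the posterior weight
#' of unneeded components towards zero, so the number of occupied clusters
#' is data-driven rather than fixed.  The fit is restarted `n_init` times
#' from different k-means initializations and the restart with the highest
#' variational lower bound (ELBO) is kept.
#'
#' @param X numeric matrix (n x d) of observations.
#' @param K_max maximum number of mixture components.
#' @param alpha0 Dirichlet weight-concentration prior; small values prune.
#' @param beta0 prior precision scaling of the component means.
#' @param cov_prior_scale scale of the Wishart covariance prior relative to
#'   the data covariance.  The prior component scale decides whether nearby
#'   tight clusters are split or a broad cloud is kept whole, and no single
#'   value suits both regimes; the default `"auto"` chooses among
#'   `c(1, 0.3, 0.1, 0.03)` by the variational lower bound (empirical
#'   Bayes / type-II maximum likelihood).  A numeric value fixes it.
#' @param n_init number of k-means restarts; best ELBO wins.
#' @param max_iter,tol iteration cap and ELBO convergence tolerance.
#' @param seed integer seed for the initializations.
#' @return A `vbgmm` object: posterior responsibilities, mixing weights,
#'   component means/covariances, hard labels (argmax responsibility, ties
#'   broken toward the lowest component index), `elbo`, and `effective_K`,
#'   the number of components that are argmax for at least one observation.
#' @export
vbgmm <- function(X, K_max = 10, alpha0 = 1 / K_max, beta0 = 1,
                  cov_prior_scale = "auto", n_init = 10, max_iter = 500,
                  tol = 1e-7, seed = 1L) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("non-finite coordinates")
  n <- nrow(X)
  if (n < K_max) stop("need at least K_max observations")
  scales <- if (identical(cov_prior_scale, "auto")) c(1, 0.3, 0.1, 0.03)
            else as.numeric(cov_prior_scale)
  best <- NULL
  for (cs in scales) {
    for (i in seq_len(n_init)) {
      fit <- vbgmm_once(X, K_max, alpha0, beta0, cs, max_iter,
                        tol, seed = derive_seed(seed, paste0("init", i)))
      if (is.null(best) || fit$elbo > best$elbo) best <- fit
    }
  }
  best
}

vbgmm_once <- function(X, K_max, alpha0, beta0, cov_prior_scale, max_iter,
                       tol, seed) {
  n <- nrow(X); d <- ncol(X)
  m0 <- colMeans(X)
  covX <- stats::cov(X) + diag(1e-8, d)
  nu0 <- d
  # prior expected component covariance = cov_prior_scale * cov(X)
  W0inv <- covX * nu0 * cov_prior_scale
  W0 <- chol2inv(chol(W0inv))
  logB0 <- log_wishart_B(W0, nu0, d)

  r <- with_seed(seed, {
    km <- stats::kmeans(X, centers = min(K_max, n - 1), nstart = 5,
                        iter.max = 50)
    r0 <- matrix(1e-8, n, K_max)
    r0[cbind(seq_len(n), km$cluster)] <- 1
    r0 / rowSums(r0)
  })

  alpha <- beta <- nu <- numeric(K_max)
  m <- matrix(0, K_max, d)
  Winv <- W <- vector("list", K_max)
  elbo_old <- -Inf; elbo <- -Inf
  for (it in seq_len(max_iter)) {
    # variational M-step
    Nk <- colSums(r) + 1e-10
    xbar <- matrix(0, K_max, d); Sk <- vector("list", K_max)
    alpha <- alpha0 + Nk
    beta <- beta0 + Nk
    nu <- nu0 + Nk
    for (k in seq_len(K_max)) {
      xbar[k, ] <- colSums(r[, k] * X) / Nk[k]
      xc <- sweep(X, 2, xbar[k, ])
      Sk[[k]] <- crossprod(xc * r[, k], xc) / Nk[k]
      m[k, ] <- (beta0 * m0 + Nk[k] * xbar[k, ]) / beta[k]
      dm <- xbar[k, ] - m0
      Winv[[k]] <- W0inv + Nk[k] * Sk[[k]] +
        (beta0 * Nk[k] / (beta0 + Nk[k])) * tcrossprod(dm)
      W[[k]] <- chol2inv(chol(Winv[[k]]))
    }
    # expected log weights / precisions
    ln_pi <- digamma(alpha) - digamma(sum(alpha))
    ln_lambda <- vapply(seq_len(K_max), function(k)
      sum(digamma((nu[k] + 1 - seq_len(d)) / 2)) + d * log(2) +
        as.numeric(determinant(W[[k]], logarithm = TRUE)$modulus), 0)
    # variational E-step
    logr <- matrix(0, n, K_max)
    for (k in seq_len(K_max)) {
      xc <- sweep(X, 2, m[k, ])
      quad <- rowSums((xc %*% W[[k]]) * xc)
      logr[, k] <- ln_pi[k] + 0.5 * ln_lambda[k] -
        0.5 * (d / beta[k] + nu[k] * quad) - d / 2 * log(2 * pi)
    }
    mx <- apply(logr, 1, max)
    lse <- mx + log(rowSums(exp(logr - mx)))
    r <- exp(logr - lse)

    # ELBO (Bishop 10.70-10.77 collapsed)
    e_loglik <- 0
    for (k in seq_len(K_max)) {
      dmk <- xbar[k, ] - m[k, ]
      e_loglik <- e_loglik + 0.5 * Nk[k] *
        (ln_lambda[k] - d / beta[k] -
           nu[k] * sum(Sk[[k]] * W[[k]]) -
           nu[k] * sum((dmk %*% W[[k]]) * dmk) - d * log(2 * pi))
    }
    e_pz_qz <- sum(r * (rep(ln_pi, each = n) - log(pmax(r, 1e-300))))
    e_ppi_qpi <- lgamma(K_max * alpha0) - K_max * lgamma(alpha0) +
      sum((alpha0 - alpha) * ln_pi) -
      (lgamma(sum(alpha)) - sum(lgamma(alpha)))
    e_pmu <- 0
    for (k in seq_len(K_max)) {
      dmk <- m[k, ] - m0
      e_pmu <- e_pmu + 0.5 * (d * log(beta0 / (2 * pi)) + ln_lambda[k] -
        d * beta0 / beta[k] - beta0 * nu[k] * sum((dmk %*% W[[k]]) * dmk)) +
        logB0 + (nu0 - d - 1) / 2 * ln_lambda[k] -
        0.5 * nu[k] * sum(W0inv * W[[k]])
    }
    e_qmu <- 0
    for (k in seq_len(K_max)) {
      H <- -log_wishart_B(W[[k]], nu[k], d) -
        (nu[k] - d - 1) / 2 * ln_lambda[k] + nu[k] * d / 2
      e_qmu <- e_qmu + 0.5 * ln_lambda[k] +
        d / 2 * log(beta[k] / (2 * pi)) - d / 2 - H
    }
    elbo <- e_loglik + e_pz_qz + e_ppi_qpi + e_pmu - e_qmu
    if (is.finite(elbo) && abs(elbo - elbo_old) < tol * abs(elbo)) break
    elbo_old <- elbo
  }

  labels <- max.col(r, ties.method = "first")
  occupied <- sort(unique(labels))
  covs <- lapply(seq_len(K_max), function(k)
    Winv[[k]] / (nu[k] - d - 1 + 1e-8))
  structure(list(responsibilities = r, labels = labels,
                 weights = as.numeric(alpha / sum(alpha)),
                 means = m, covariances = covs,
                 alpha = alpha, beta = beta, nu = nu, Winv = Winv,
                 K_max = K_max, effective_K = length(occupied),
                 occupied = occupied, d = d, iterations = it, elbo = elbo,
                 cov_prior_scale = cov_prior_scale),
            class = "vbgmm")
}

log_wishart_B <- function(W, nu, d) {
  -(nu / 2) * as.numeric(determinant(W, logarithm = TRUE)$modulus) -
    (nu * d / 2) * log(2) - (d * (d - 1) / 4) * log(pi) -
    sum(lgamma((nu + 1 - seq_len(d)) / 2))
}

#' @export
print.vbgmm <- function(x, ...) {
  cat(sprintf("<vbgmm> K_max = %d, effective components = %d (ELBO %.2f)\n",
              x$K_max, x$effective_K, x$elbo))
  invisible(x)
}

# Responsibilities of new points under a fitted vbgmm (same variational
# predictive form as the E-step).
vbgmm_responsibility <- function(fit, X) {
  X <- matrix(X, ncol = fit$d)
  n <- nrow(X); d <- fit$d; K <- fit$K_max
  ln_pi <- digamma(fit$alpha) - digamma(sum(fit$alpha))
  logr <- matrix(0, n, K)
  for (k in seq_len(K)) {
    Wk <- chol2inv(chol(fit$Winv[[k]]))
    ln_lambda <- sum(digamma((fit$nu[k] + 1 - seq_len(d)) / 2)) +
      d * log(2) + as.numeric(determinant(Wk, logarithm = TRUE)$modulus)
    xc <- sweep(X, 2, fit$means[k, ], check.margin = FALSE)
    quad <- rowSums((xc %*% Wk) * xc)
    logr[, k] <- ln_pi[k] + 0.5 * ln_lambda -
      0.5 * (d / fit$beta[k] + fit$nu[k] * quad) - d / 2 * log(2 * pi)
  }
  logr <- logr - apply(logr, 1, max)
  exp(logr) / rowSums(exp(logr))
}
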