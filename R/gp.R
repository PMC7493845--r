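# Gaussian-process surrogate: ARD Matern 5/2 kernel on inputs rescaled to
# the unit box, observations standardized internally, hyperparameters fit
# by marginal-likelihood maximization.

matern52 <- function(A, B, lengthscales, amp2) {
  # A: n x d, B: m x d, returns n x m covariance
  As <- sweep(A, 2, lengthscales, "/")
  Bs <- sweep(B, 2, lengthscales, "/")
  d2 <- outer(rowSums(As^2), rowSums(Bs^2), "+") - 2 * tcrossprod(As, Bs)
  r <- sqrt(pmax(d2, 0))
  amp2 * (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r)
}

.gp_chol <- function(K) {
  # Cholesky with jitter escalation; singular after escalation -> error
  jit <- 1e-10
  for (i in 1:6) {
    L <- tryCatch(chol(K + diag(jit, nrow(K))), error = function(e) NULL)
    if (!is.null(L)) return(L)
    jit <- jit * 100
  }
  stop("covariance matrix is numerically singular even after jitter escalation")
}

.gp_nll <- function(par, Z, y) {
  amp2 <- exp(2 * par[1])
  ls <- exp(par[2:(1 + ncol(Z))])
  sn2 <- exp(2 * par[length(par)])
  K <- matern52(Z, Z, ls, amp2) + diag(sn2, nrow(Z))
  L <- tryCatch(chol(K + diag(1e-10, nrow(Z))), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  alpha <- backsolve(L, forwardsolve(t(L), y))
  as.numeric(0.5 * crossprod(y, alpha) + sum(log(diag(L))) + 0.5 * length(y) * log(2 * pi))
}

#' Fit a Gaussian-process surrogate
#'
#' Fits `f ~ GP(u, K)` with an ARD Matern 5/2 kernel to observed inputs
#' `Z` (assumed rescaled to the unit box) and losses `y`. The prior mean
#' `u` is the sample mean of `y`; observations are standardized
#' internally. Unless fixed values are supplied, the kernel amplitude,
#' per-dimension length scales and noise standard deviation are chosen by
#' maximizing the log marginal likelihood from a small fixed set of
#' starts (deterministic). The noise variance is floored at 1e-10.
#'
#' @param Z numeric matrix of observed inputs, one row per observation.
#' @param y numeric vector of observed losses.
#' @param amplitude,lengthscales,sigma_n optional fixed hyperparameters on
#'   the standardized-output scale; all three must be given to skip the
#'   marginal-likelihood fit.
#' @param start optional warm-start parameter vector
#'   `c(log amplitude, log lengthscales, log sigma_n)` for the
#'   marginal-likelihood fit (e.g. the previous iteration's fit).
#' @return Object of class `aneuscan_gp`.
#' @export
gp_fit <- function(Z, y, amplitude = NULL, lengthscales = NULL, sigma_n = NULL,
                   start = NULL) {
  Z <- as.matrix(Z)
  if (nrow(Z) < 1L) stop("at least one observation is required")
  if (nrow(Z) != length(y)) stop("Z and y sizes differ")
  y_mean <- mean(y)
  y_sd <- stats::sd(y)
  if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1
  ys <- (y - y_mean) / y_sd
  d <- ncol(Z)
  fixed <- !is.null(amplitude) && !is.null(lengthscales) && !is.null(sigma_n)
  if (fixed) {
    amp2 <- amplitude^2; ls <- rep_len(lengthscales, d); sn <- max(sigma_n, 1e-5)
  } else {
    starts <- list(c(0, rep(log(0.3), d), log(1e-3)),
                   c(0, rep(log(1), d), log(1e-2)))
    lower <- c(log(1e-3), rep(log(0.03), d), log(1e-5))
    upper <- c(log(1e3), rep(log(3), d), log(1))
    if (!is.null(start)) starts <- list(pmin(pmax(start, lower), upper))
    best <- NULL
    for (p0 in starts) {
      fit <- tryCatch(
        stats::optim(p0, .gp_nll, Z = Z, y = ys, method = "L-BFGS-B",
                     lower = lower, upper = upper,
                     control = list(maxit = 40)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    }
    if (is.null(best)) { par <- starts[[1]] } else par <- best$par
    amp2 <- exp(2 * par[1]); ls <- exp(par[2:(1 + d)]); sn <- exp(par[length(par)])
  }
  sn2 <- max(sn^2, 1e-10)
  K <- matern52(Z, Z, ls, amp2) + diag(sn2, nrow(Z))
  L <- .gp_chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  structure(list(Z = Z, y = y, ys = ys, y_mean = y_mean, y_sd = y_sd,
                 amp2 = amp2, lengthscales = ls, sigma_n = sqrt(sn2),
                 par = c(log(amp2) / 2, log(ls), log(sqrt(sn2))),
                 L = L, alpha = alpha),
            class = "aneuscan_gp")
}

# Rebuild the factorization with the kernel amplitude scaled by `factor^2`
# (used by the overexploitation safeguard to force exploration).
gp_scale_amplitude <- function(model, factor) {
  model$amp2 <- model$amp2 * factor^2
  K <- matern52(model$Z, model$Z, model$lengthscales, model$amp2) +
    diag(max(model$sigma_n^2, 1e-10), nrow(model$Z))
  model$L <- .gp_chol(K)
  model$alpha <- backsolve(model$L, forwardsolve(t(model$L), model$ys))
  model
}

#' GP posterior mean and variance
#'
#' Predictive distribution at query points:
#' `u_hat = k(z)' (K + sn^2 I)^-1 y` and
#' `s2_hat = k(z,z) - k(z)' (K + sn^2 I)^-1 k(z)`, mapped back to the raw
#' output scale; the variance is clamped at 0.
#'
#' @param model an `aneuscan_gp` from [gp_fit()].
#' @param query numeric vector (one point) or matrix (one row per point)
#'   on the same input scale as the training inputs.
#' @return List with numeric vectors `mean` and `variance`.
#' @export
gp_posterior <- function(model, query) {
  stopifnot(inherits(model, "aneuscan_gp"))
  if (inherits(query, "aneuscan_params")) query <- c(query$s, query$tau)
  Q <- if (is.matrix(query)) query else matrix(query, nrow = 1)
  ks <- matern52(model$Z, Q, model$lengthscales, model$amp2)  # n x m
  mu <- drop(crossprod(ks, model$alpha))
  v <- forwardsolve(t(model$L), ks)
  var_s <- pmax(model$amp2 - colSums(v^2), 0)
  list(mean = model$y_mean + model$y_sd * mu,
       variance = model$y_sd^2 * var_s)
}

#' Expected improvement (minimization)
#'
#' Closed-form expected improvement of a Gaussian predictive distribution
#' over the best observed loss:
#' `EI = (f_best - mean) * Phi(d/s) + s * phi(d/s)` with
#' `d = f_best - mean`, `s = sqrt(variance)`. For `variance = 0` it
#' degenerates to `max(f_best - mean, 0)`.
#'
#' @param mean,variance posterior mean(s) and variance(s); variance >= 0.
#' @param f_best best (smallest) observed loss.
#' @return Non-negative expected improvement value(s).
#' @export
expected_improvement <- function(mean, variance, f_best) {
  if (any(variance < 0)) stop("variance must be non-negative")
  s <- sqrt(variance)
  d <- f_best - mean
  out <- pmax(d, 0)
  pos <- s > 0
  if (any(pos)) {
    z <- d[pos] / s[pos]
    out[pos] <- d[pos] * stats::pnorm(z) + s[pos] * stats::dnorm(z)
  }
  pmax(out, 0)
}
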