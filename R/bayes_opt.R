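# Bayesian optimization of the filter parameters (s, tau): GP surrogate +
# expected improvement, with an overexploitation safeguard that inflates
# the kernel amplitude to force exploration.

.check_bounds <- function(bounds) {
  if (!is.list(bounds) || !all(c("s", "tau") %in% names(bounds)))
    stop("bounds must be a list with elements 's' and 'tau'")
  for (nm in c("s", "tau")) {
    b <- bounds[[nm]]
    if (length(b) != 2L || !all(is.finite(b)) || b[1] >= b[2])
      stop("bounds$", nm, " must be c(lower, upper) with lower < upper")
  }
  bounds
}

#' Default search box for the filter parameters
#'
#' Scale from 0.5 (sub-voxel kernels are degenerate) to 20 voxels, cutoff
#' fraction from 0.7 to 1.
#' @return List with elements `s` and `tau`.
#' @export
default_bounds <- function() list(s = c(0.5, 20), tau = c(0.7, 1))

.scale01 <- function(Z, bounds) {
  lo <- c(bounds$s[1], bounds$tau[1]); hi <- c(bounds$s[2], bounds$tau[2])
  sweep(sweep(Z, 2, lo, "-"), 2, hi - lo, "/")
}

.unscale01 <- function(Z01, bounds) {
  lo <- c(bounds$s[1], bounds$tau[1]); hi <- c(bounds$s[2], bounds$tau[2])
  sweep(sweep(Z01, 2, hi - lo, "*"), 2, lo, "+")
}

# Maximize EI over the unit box: random scan then local polish.
.propose_ei <- function(model, f_best, n_scan = 2048L) {
  d <- ncol(model$Z)
  scan <- matrix(runif(n_scan * d), ncol = d)
  post <- gp_posterior(model, scan)
  ei <- expected_improvement(post$mean, post$variance, f_best)
  z0 <- scan[which.max(ei), ]
  neg_ei <- function(z) {
    p <- gp_posterior(model, matrix(z, nrow = 1))
    -expected_improvement(p$mean, p$variance, f_best)
  }
  fit <- tryCatch(
    stats::optim(z0, neg_ei, method = "L-BFGS-B", lower = rep(0, d), upper = rep(1, d),
                 control = list(maxit = 50)),
    error = function(e) NULL)
  if (!is.null(fit) && is.finite(fit$value) && -fit$value >= max(ei)) fit$par else z0
}

#' Overexploitation safeguard
#'
#' An EI candidate whose posterior standard deviation `sigmaF(z)` falls
#' below `sigma * t_sigma` (with `sigma` the model's noise standard
#' deviation) is considered overexploited. The kernel amplitude is then
#' inflated -- first by the current iteration index, then by successive
#' factors of 10 -- and a new candidate proposed, up to five retries;
#' after that the last candidate is returned with a flag.
#'
#' @param model an `aneuscan_gp`.
#' @param state list with `t_sigma` (exploration ratio, positive),
#'   `iteration` (current iteration index), optional `f_best` and
#'   `n_scan`.
#' @param candidate numeric input-scale (unit box) candidate point.
#' @return List with `candidate`, `retries` (0..5), `flagged` (TRUE if the
#'   retry budget was exhausted) and the possibly inflated `model`.
#' @export
overexploit_adjust <- function(model, state, candidate) {
  t_sigma <- state$t_sigma %||% 0.5
  f_best <- state$f_best %||% min(model$y)
  n_scan <- state$n_scan %||% 2048L
  noise_sd <- model$y_sd * model$sigma_n
  retries <- 0L
  repeat {
    sF <- sqrt(gp_posterior(model, matrix(candidate, nrow = 1))$variance)
    if (sF >= noise_sd * t_sigma)
      return(list(candidate = candidate, retries = retries, flagged = FALSE, model = model))
    if (retries >= 5L)
      return(list(candidate = candidate, retries = retries, flagged = TRUE, model = model))
    factor <- if (retries == 0L) max(state$iteration %||% 2, 2) else 10
    model <- gp_scale_amplitude(model, factor)
    candidate <- .propose_ei(model, f_best, n_scan)
    retries <- retries + 1L
  }
}

#' Bayesian optimization of a loss over the (s, tau) box
#'
#' Sequential model-based minimization: a small maximin Latin hypercube
#' initial design, then GP-fit / EI-maximization iterations with the
#' overexploitation safeguard, for exactly `budget` objective
#' evaluations. Deterministic given `seed`.
#'
#' @param objective function taking an [filter_params()] object and
#'   returning a finite loss (non-finite values are recorded as a large
#'   penalty and logged).
#' @param bounds search box, see [default_bounds()].
#' @param budget total number of objective evaluations (>= `n_init`).
#' @param seed integer seed controlling all randomness of the run.
#' @param n_init number of initial design points.
#' @param t_sigma exploration ratio of the overexploitation rule.
#' @param n_scan size of the random scan used to seed EI maximization.
#' @return List with `best` (an [filter_params()]), `best_loss`, and
#'   `trace`, a data.frame with one row per evaluation: `iter`, `s`,
#'   `tau`, `loss`, `best` (best-so-far loss, non-increasing) and
#'   `overexploit`.
#' @export
bayes_optimize <- function(objective, bounds = default_bounds(), budget = 50L,
                           seed = 1L, n_init = 4L, t_sigma = 0.5, n_scan = 2048L) {
  bounds <- .check_bounds(bounds)
  budget <- as.integer(budget); n_init <- as.integer(n_init)
  if (budget < n_init) stop("budget must be at least n_init (", n_init, ")")
  eval_obj <- function(z) {
    p <- filter_params(z[1], min(max(z[2], bounds$tau[1]), bounds$tau[2]))
    val <- tryCatch(objective(p), error = function(e) NaN)
    if (!is.finite(val)) {
      message("objective returned a non-finite value at (s=", signif(z[1], 4),
              ", tau=", signif(z[2], 4), "); recording penalty")
      val <- 1e10
    }
    val
  }
  withr::with_seed(seed, {
    Z01 <- lhs::maximinLHS(n_init, 2)
    Z <- .unscale01(Z01, bounds)
    y <- apply(Z, 1, eval_obj)
    over <- rep(FALSE, n_init)
    warm <- NULL
    if (budget > n_init) {
      for (it in (n_init + 1):budget) {
        model <- gp_fit(Z01, y, start = warm)
        warm <- model$par
        cand <- .propose_ei(model, min(y), n_scan)
        adj <- overexploit_adjust(model, list(t_sigma = t_sigma, iteration = it,
                                              f_best = min(y), n_scan = n_scan), cand)
        z01 <- pmin(pmax(adj$candidate, 0), 1)
        # avoid exact duplicates, which make the covariance singular
        if (min(colSums((t(Z01) - z01)^2)) < 1e-16) z01 <- runif(2)
        z <- drop(.unscale01(matrix(z01, nrow = 1), bounds))
        Z01 <- rbind(Z01, z01); Z <- rbind(Z, z)
        y <- c(y, eval_obj(z))
        over <- c(over, adj$flagged || adj$retries > 0)
      }
    }
    best_i <- which.min(y)
    trace <- data.frame(iter = seq_len(budget), s = Z[, 1], tau = Z[, 2],
                        loss = y, best = cummin(y), overexploit = over)
    list(best = filter_params(Z[best_i, 1], min(max(Z[best_i, 2], bounds$tau[1]), bounds$tau[2])),
         best_loss = y[best_i], trace = trace)
  })
}

#' Reciprocal-response loss for a volume
#'
#' Returns a closure mapping filter parameters to
#' `1 / (eps + max(Bp))`, the reciprocal of the volume-maximum filter
#' response: the quantity the optimizer minimizes so that the filter's
#' peak response (where detection seeds) is as strong as possible. The
#' small `eps` keeps the loss finite on response-free (e.g. constant)
#' volumes.
#'
#' @param volume a preprocessed [as_volume()] object.
#' @param variant passed to [filter_response()].
#' @param eps stabilizer, default 1e-12.
#' @return Function of an [filter_params()] object returning a positive
#'   loss.
#' @export
reciprocal_loss <- function(volume, variant = "printed", eps = 1e-12) {
  stopifnot(is_volume(volume))
  force(variant); force(eps)
  function(params) 1 / (eps + max(filter_response(volume, params, variant)$values))
}
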