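# GP surrogate, expected improvement, overexploitation safeguard, and the
# optimization loop.

test_that("GP posterior interpolates noise-free observations", {
  m <- gp_fit(matrix(c(0.3, 0.6), 1, 2), 1.7,
              amplitude = 1, lengthscales = 0.3, sigma_n = 0)
  p <- gp_posterior(m, c(0.3, 0.6))
  expect_equal(p$mean, 1.7, tolerance = 1e-6)
  expect_lt(p$variance, 1e-6)
})

test_that("GP posterior far from data recovers the prior", {
  Z <- matrix(runif(10, 0, 0.1), 5, 2)
  withr::with_seed(2, y <- rnorm(5, 3, 0.5))
  m <- gp_fit(Z, y, amplitude = 1, lengthscales = 0.05, sigma_n = 1e-4)
  p <- gp_posterior(m, c(1e6, 1e6))
  expect_equal(p$mean, mean(y), tolerance = 1e-6)      # prior mean
  expect_equal(p$variance, var(y) * 1, tolerance = 1e-3)  # k(z,z) = amp^2 (std scale)
})

test_that("GP posterior matches a dense explicit-inverse solve", {
  withr::with_seed(8, {
    Z <- matrix(runif(10), 5, 2)
    y <- rnorm(5)
    amp <- 1.3; ls <- c(0.4, 0.25); sn <- 0.05
    m <- gp_fit(Z, y, amplitude = amp, lengthscales = ls, sigma_n = sn)
    q <- matrix(runif(6), 3, 2)
    got <- gp_posterior(m, q)
    # dense route on standardized outputs, explicit solve()
    ys <- (y - mean(y)) / sd(y)
    K <- aneuscan:::matern52(Z, Z, ls, amp^2) + diag(sn^2, 5) + diag(1e-10, 5)
    Kinv <- solve(K)
    ks <- aneuscan:::matern52(Z, q, ls, amp^2)
    mu <- mean(y) + sd(y) * drop(crossprod(ks, Kinv %*% ys))
    va <- sd(y)^2 * pmax(amp^2 - colSums(ks * (Kinv %*% ks)), 0)
    expect_equal(got$mean, mu, tolerance = 1e-8)
    expect_equal(got$variance, va, tolerance = 1e-8)
  })
})

test_that("expected improvement: closed form, degenerate cases, quadrature", {
  expect_equal(expected_improvement(2, 0, 1), 0)       # no improvement, no variance
  expect_equal(expected_improvement(1, 0, 1), 0)
  expect_equal(expected_improvement(0.25, 0, 1), 0.75) # deterministic improvement
  # quadrature of the integral form: int_{-inf}^{f'} (f' - f) N(f; u, s2) df
  quad_ei <- function(u, s2, fb) {
    stats::integrate(function(f) (fb - f) * dnorm(f, u, sqrt(s2)),
                     lower = u - 12 * sqrt(s2), upper = fb)$value
  }
  for (case in list(c(0, 1, 0), c(0.5, 0.2, 0.3), c(-1, 2, -0.5))) {
    expect_equal(expected_improvement(case[1], case[2], case[3]),
                 quad_ei(case[1], case[2], case[3]), tolerance = 1e-6)
  }
  expect_equal(expected_improvement(0, 1, 0), dnorm(0), tolerance = 1e-12)
  expect_error(expected_improvement(0, -1, 0), "non-negative")
})

test_that("overexploitation: explored candidates pass through unchanged", {
  withr::with_seed(4, {
    Z <- matrix(runif(12), 6, 2)
    y <- rowSums(Z^2)
    m <- gp_fit(Z, y, amplitude = 1, lengthscales = 0.3, sigma_n = 1e-4)
    far <- c(0.95, 0.05)  # far from data: posterior sd is large
    res <- overexploit_adjust(m, list(t_sigma = 0.5, iteration = 7), far)
    expect_identical(res$candidate, far)
    expect_identical(res$retries, 0L)
    expect_false(res$flagged)
    # noise-free model: sigma = 0, the condition sigmaF < 0 never fires
    m0 <- gp_fit(Z, y, amplitude = 1, lengthscales = 0.3, sigma_n = 0)
    res0 <- overexploit_adjust(m0, list(t_sigma = 0.5, iteration = 7), Z[1, ])
    expect_identical(res0$retries, 0L)
  })
})

test_that("overexploitation retries exactly five times when forced", {
  withr::with_seed(6, {
    # huge exploration ratio: sigma * t_sigma exceeds any posterior sd
    # even after amplitude escalation, so every candidate is judged
    # overexploited
    Z <- matrix(runif(8), 4, 2)
    y <- rnorm(4)
    m <- gp_fit(Z, y, amplitude = 0.5, lengthscales = 0.5, sigma_n = 10)
    res <- overexploit_adjust(m, list(t_sigma = 1e7, iteration = 3), c(0.5, 0.5))
    expect_identical(res$retries, 5L)
    expect_true(res$flagged)
    # amplitude was escalated: first by the iteration count, then by 10s
    expect_gt(res$model$amp2 / m$amp2, (3 * 10^4)^2 * 0.99)
  })
})

test_that("optimizer finds the quadratic bowl minimum within budget", {
  obj <- function(p) (p$s - 5)^2 + (p$tau - 0.8)^2
  res <- bayes_optimize(obj, budget = 50, seed = 123)
  expect_lt(abs(res$best$s - 5), 0.3)
  expect_lt(abs(res$best$tau - 0.8), 0.3)
  expect_lt(res$best_loss, 0.05)
})

test_that("optimizer contract: budget, trace, determinism, bounds", {
  obj <- function(p) (p$s - 5)^2 + (p$tau - 0.8)^2
  # degenerate budget: initial design only
  r4 <- bayes_optimize(obj, budget = 4, seed = 3)
  expect_identical(nrow(r4$trace), 4L)
  expect_equal(r4$best_loss, min(r4$trace$loss))
  # full run: exact budget, monotone best-so-far, candidates in bounds
  r <- bayes_optimize(obj, budget = 20, seed = 5)
  expect_identical(nrow(r$trace), 20L)
  expect_true(all(diff(r$trace$best) <= 0))
  expect_true(all(r$trace$s >= 0.5 & r$trace$s <= 20))
  expect_true(all(r$trace$tau >= 0.7 & r$trace$tau <= 1))
  expect_equal(r$trace$best, cummin(r$trace$loss))
  # determinism: identical traces under the same seed
  r2 <- bayes_optimize(obj, budget = 20, seed = 5)
  expect_identical(r$trace, r2$trace)
})

test_that("non-finite objective values are penalized, not fatal", {
  obj <- function(p) if (p$s > 10) NaN else (p$s - 5)^2
  expect_message(r <- bayes_optimize(obj, budget = 12, seed = 9), "non-finite")
  expect_true(all(is.finite(r$trace$loss)))
  expect_lt(r$best_loss, 1e9)
})

test_that("BO beats random search on the toy objective over 20 seeds", {
  obj <- function(p) (p$s - 5)^2 + (p$tau - 0.8)^2
  bo <- numeric(20); rs <- numeric(20)
  for (i in 1:20) {
    bo[i] <- bayes_optimize(obj, budget = 25, seed = 100 + i)$best_loss
    rs[i] <- withr::with_seed(100 + i, {
      s <- runif(25, 0.5, 20); tau <- runif(25, 0.7, 1)
      min((s - 5)^2 + (tau - 0.8)^2)
    })
  }
  expect_lt(median(bo), median(rs))
})

test_that("reciprocal loss is finite on empty volumes and prefers blobs", {
  flat <- as_volume(array(0.5, c(12, 12, 12)))
  loss_flat <- suppressWarnings(reciprocal_loss(flat))
  expect_equal(loss_flat(filter_params(2, 0.8)), 1e12)
  tube <- tube_volume(n = 40, tube_r = 3)
  tube_sphere <- tube_volume(n = 40, tube_r = 3, sphere_r = 4)
  p <- filter_params(4, 0.8)
  # adding a bright sphere lowers the loss at matched scale
  expect_lt(reciprocal_loss(tube_sphere)(p), reciprocal_loss(tube)(p))
  # matched scale beats far-off scale on a sphere-bearing phantom
  expect_lt(reciprocal_loss(tube_sphere)(filter_params(4, 0.8)),
            reciprocal_loss(tube_sphere)(filter_params(16, 0.8)))
})
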