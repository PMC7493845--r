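# Spherical-structure (blob) enhancement from scale-normalized Hessian
# eigenvalues. Axis labels follow the volume convention: axis 1 = z,
# axis 2 = y, axis 3 = x; component names use the physical axis letters.

# Discrete Gaussian window plus derivative windows. The derivative
# operators are central differences of the sampled, sum-normalized
# Gaussian, so differentiation commutes exactly with the discrete
# smoothing and mixed partials are symmetric by construction.
gauss_windows <- function(s) {
  r <- max(1L, as.integer(ceiling(3 * s)))
  tt <- seq(-r, r)
  g <- exp(-tt^2 / (2 * s^2))
  g <- g / sum(g)
  lookup <- function(idx) ifelse(abs(idx) > r, 0, g[pmin(pmax(idx, -r), r) + r + 1])
  te <- seq(-(r + 1), r + 1)
  d1 <- (lookup(te - 1) - lookup(te + 1)) / 2   # correlation window for d/dt
  d2 <- lookup(te - 1) - 2 * lookup(te) + lookup(te + 1)
  list(g = g, d1 = d1, d2 = d2, radius = r)
}

#' Scale-normalized Hessian of a volume
#'
#' Computes the six unique second-derivative fields of the volume smoothed
#' by a Gaussian of standard deviation `s` voxels, multiplied by the
#' scale-normalization factor `s^2` so that responses are comparable across
#' scales. Derivatives are implemented as central differences of the
#' discrete Gaussian kernel (separable convolution, reflected boundaries).
#' Scales below 0.5 voxels are clipped to 0.5, where the kernel is still
#' meaningful.
#'
#' @param volume a preprocessed [as_volume()] object.
#' @param s scale (Gaussian standard deviation), in voxels; must be > 0.
#' @return An object of class `aneuscan_hessian`: list with component
#'   fields `Hxx`, `Hyy`, `Hzz`, `Hxy`, `Hxz`, `Hyz` (3D arrays) and
#'   `scale`.
#' @export
compute_hessian <- function(volume, s) {
  stopifnot(is_volume(volume))
  if (length(s) != 1L || !is.finite(s) || s <= 0) stop("scale s must be a positive number")
  s <- max(s, 0.5)
  w <- gauss_windows(s)
  d <- dim(volume$data)
  x <- as.vector(volume$data)
  cv <- function(v, win, axis) conv3d_axis(v, d, win, axis)
  # axis 1 = z, axis 2 = y, axis 3 = x
  Sz <- cv(x, w$g, 1); Dz <- cv(x, w$d1, 1); Tz <- cv(x, w$d2, 1)
  SzSy <- cv(Sz, w$g, 2); SzDy <- cv(Sz, w$d1, 2); SzTy <- cv(Sz, w$d2, 2)
  DzSy <- cv(Dz, w$g, 2); DzDy <- cv(Dz, w$d1, 2)
  TzSy <- cv(Tz, w$g, 2)
  # fold the s^2 scale normalization into the final-pass windows
  s2 <- s^2
  g3 <- s2 * w$g; d13 <- s2 * w$d1; d23 <- s2 * w$d2
  comp <- function(v) { dim(v) <- d; v }
  structure(list(
    Hxx = comp(cv(SzSy, d23, 3)),
    Hyy = comp(cv(SzTy, g3, 3)),
    Hzz = comp(cv(TzSy, g3, 3)),
    Hxy = comp(cv(SzDy, d13, 3)),
    Hxz = comp(cv(DzSy, d13, 3)),
    Hyz = comp(cv(DzDy, g3, 3)),
    scale = s, dim = d
  ), class = "aneuscan_hessian")
}

#' Magnitude-sorted Hessian eigenvalues
#'
#' Per-voxel eigenvalues of the symmetric 3x3 Hessian, ordered
#' `|l1| <= |l2| <= |l3|` with ties broken by signed value ascending.
#'
#' @param hessian an `aneuscan_hessian` from [compute_hessian()].
#' @return An object of class `aneuscan_eigs`: list of 3D arrays `l1`,
#'   `l2`, `l3` plus `scale`.
#' @export
eigenvalues_sorted <- function(hessian) {
  stopifnot(inherits(hessian, "aneuscan_hessian"))
  d <- hessian$dim
  # matrix rows/cols in (z, y, x) axis order
  e <- eig3x3_sorted_cpp(as.vector(hessian$Hzz), as.vector(hessian$Hyy),
                         as.vector(hessian$Hxx), as.vector(hessian$Hyz),
                         as.vector(hessian$Hxz), as.vector(hessian$Hxy))
  structure(list(l1 = array(e$l1, d), l2 = array(e$l2, d), l3 = array(e$l3, d),
                 scale = hessian$scale),
            class = "aneuscan_eigs")
}

#' Filter parameter pair (s, tau)
#'
#' The two knobs of the spherical-structure filter: the scale `s` (voxels)
#' and the cutoff fraction `tau` regularizing the largest eigenvalue. The
#' search box used by the optimizer is s in (0, 20] (clipped below at 0.5)
#' and tau in [0.7, 1].
#'
#' @param s positive scale in voxels.
#' @param tau cutoff fraction in `[0.7, 1]`.
#' @return An object of class `aneuscan_params`.
#' @export
filter_params <- function(s, tau) {
  if (length(s) != 1L || !is.finite(s) || s <= 0) stop("s must be a positive number")
  if (length(tau) != 1L || !is.finite(tau) || tau < 0.7 || tau > 1)
    stop("tau must lie in [0.7, 1]")
  structure(list(s = as.numeric(s), tau = as.numeric(tau)), class = "aneuscan_params")
}

#' Blobness response from sign-adjusted eigenvalues
#'
#' Evaluates the spherical-structure response. Bright blobs on a dark
#' background have three negative Hessian eigenvalues, so the caller passes
#' *sign-adjusted* (negated) eigenvalues, making bright-blob voxels
#' positive triples. With `lr` the cutoff-regularized largest eigenvalue,
#'
#' \deqn{B_1 = \tfrac{2}{3}\left[\lambda_1^2 \lambda_\rho
#'   \left(\tfrac{3}{2\lambda_1+\lambda_\rho}\right)^3 +
#'   \tfrac{\lambda_1^2}{|\lambda_\rho|} +
#'   \sqrt{\lambda_1\lambda_\rho}\right],\qquad
#'   B_p = \frac{e^{B_1}-1}{e-1},}
#'
#' where \eqn{\lambda_\rho = \lambda_3} if \eqn{\lambda_3 >
#' \tau\,\Lambda_3} and \eqn{\tau\,\Lambda_3} otherwise, with
#' \eqn{\Lambda_3} the volume-wide extremum of adjusted \eqn{\lambda_3} at
#' this scale. The response is forced to 0 outside the bright-sphere
#' eigenvalue pattern, i.e. wherever any adjusted eigenvalue or
#' \eqn{\lambda_\rho} is \eqn{\le 0} (the first term's denominator
#' \eqn{2\lambda_1+\lambda_\rho} passes through zero for negative
#' \eqn{\lambda_1}, so non-blob voxels must be excluded, exactly as the
#' classical volume-ratio filter excludes \eqn{\lambda_2 \le 0}); the
#' square-root argument is clamped at 0; the removable singularity at
#' \eqn{2\lambda_1+\lambda_\rho = 0} is set to 0; and the final response
#' is floored at 0. An ideal bright
#' sphere with adjusted eigenvalues (1, 1, 1) and \eqn{\lambda_\rho = 1}
#' gives \eqn{B_1 = 2}, \eqn{B_p = e + 1 \approx 3.718}: the response is
#' deliberately not bounded by 1. An ideal tube cross-section
#' (\eqn{\lambda_1 = 0}) gives 0.
#'
#' `variant = "jerman"` substitutes the classical bounded volume-ratio
#' enhancement (built on \eqn{\lambda_2}) for comparison runs.
#'
#' @param eigs an `aneuscan_eigs` whose eigenvalue fields are already
#'   sign-adjusted (negated) for bright structures, or a list with elements
#'   `l1`, `l2`, `l3`.
#' @param tau cutoff fraction in `[0.7, 1]`.
#' @param l3_extremum volume-wide maximum of the adjusted `l3` at this
#'   scale.
#' @param variant `"printed"` (default) or `"jerman"`.
#' @return Array of non-negative per-voxel responses, with attribute
#'   `lrho_cut = tau * l3_extremum`.
#' @export
blobness <- function(eigs, tau, l3_extremum, variant = c("printed", "jerman")) {
  variant <- match.arg(variant)
  if (length(tau) != 1L || !is.finite(tau) || tau < 0.7 || tau > 1)
    stop("tau must lie in [0.7, 1]")
  l1 <- eigs$l1; l2 <- eigs$l2; l3 <- eigs$l3
  cut <- tau * l3_extremum
  lr <- pmax(l3, cut)                      # lr = l3 if l3 > tau*extremum, else the cutoff
  valid <- (l3 > 0) & (lr > 0) & (l1 > 0)
  if (variant == "jerman") {
    denom <- 2 * l2 + lr
    e <- 3 / denom
    bp <- l2 * l2 * lr * e * e * e
    bp[abs(denom) < 1e-12] <- 0
    bp[l2 >= lr / 2 & l2 > 0] <- 1
    bp[l2 <= 0 | !valid] <- 0
    bp <- pmax(bp, 0)
  } else {
    denom <- 2 * l1 + lr
    e <- 3 / denom
    t1 <- l1 * l1 * lr * e * e * e
    t1[abs(denom) < 1e-12] <- 0
    t2 <- l1 * l1 / abs(lr)
    t2[lr == 0] <- 0
    t3 <- sqrt(pmax(l1 * lr, 0))
    b1 <- (2 / 3) * (t1 + t2 + t3)
    bp <- expm1(b1) / (exp(1) - 1)
    bp[!valid] <- 0
    bp <- pmax(bp, 0)
  }
  if (is.array(l1)) bp <- array(bp, dim(l1))
  attr(bp, "lrho_cut") <- cut
  bp
}

#' Spherical-structure filter response of a volume
#'
#' Composes the pipeline at a fixed parameter pair: scale-normalized
#' Hessian at `params$s`, magnitude-sorted eigenvalues, sign adjustment
#' (negation, so bright blobs give positive triples), the per-scale
#' extremum of adjusted `l3`, and the per-voxel blobness.
#'
#' @param volume a preprocessed [as_volume()] object.
#' @param params an [filter_params()] pair.
#' @param variant passed to [blobness()].
#' @return Object of class `aneuscan_response`: list with `values` (3D
#'   non-negative array), `params`, `lrho_cut`, `l3_max`, `spacing`.
#' @export
filter_response <- function(volume, params, variant = c("printed", "jerman")) {
  variant <- match.arg(variant)
  stopifnot(is_volume(volume), inherits(params, "aneuscan_params"))
  if (diff(range(volume$data)) == 0) {
    # a constant field has no structure; short-circuit to an exact zero
    # response rather than accumulate rounding residue
    return(structure(list(values = array(0, dim(volume$data)), params = params,
                          lrho_cut = 0, l3_max = 0, spacing = volume$spacing),
                     class = "aneuscan_response"))
  }
  if (variant == "printed") {
    # fused C++ path (identical to the composed route, asserted by tests)
    s <- max(params$s, 0.5)
    w <- gauss_windows(s)
    r <- filter_response_cpp(as.vector(volume$data), dim(volume$data),
                             w$g, w$d1, w$d2, s^2, params$tau)
    bp <- r$bp; dim(bp) <- dim(volume$data)
    m <- r$l3_max; cut <- r$lrho_cut
  } else {
    h <- compute_hessian(volume, params$s)
    eigs <- eigenvalues_sorted(h)
    adj <- list(l1 = -eigs$l1, l2 = -eigs$l2, l3 = -eigs$l3)
    m <- max(adj$l3)
    bp <- blobness(adj, params$tau, m, variant = variant)
    cut <- attr(bp, "lrho_cut")
  }
  structure(list(values = bp, params = params,
                 lrho_cut = cut, l3_max = m,
                 spacing = volume$spacing),
            class = "aneuscan_response")
}

#' @export
print.aneuscan_response <- function(x, ...) {
  cat(sprintf("<aneuscan_response> s = %.3g, tau = %.3g, max Bp = %.4g, lrho cutoff = %.4g\n",
              x$params$s, x$params$tau, max(x$values), x$lrho_cut))
  invisible(x)
}
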