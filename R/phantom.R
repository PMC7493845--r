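# Synthetic vascular phantoms: bright curved tubes (vessels) with attached
# bright spheres (aneurysms) on a dark background, plus Gaussian noise.
# Contrast-filled structures are uniformly bright inside the lumen with a
# soft Gaussian edge of roughly point-spread-function width (binary edges
# would have impulse-like second derivatives, fully soft Gaussian bumps
# would be far blurrier than subtraction angiography). The profile is
# exp(-max(0, d - rc)^2 / (2 se^2)) with the flat core radius rc chosen so
# the half-maximum isosurface sits at the nominal radius.

.edge_sigma <- 1.0

# Max-composite a soft-edged ball of the given nominal radius and peak
# intensity around a real-space center into `field`.
.stamp_ball <- function(field, center, radius, intensity = 1) {
  d <- dim(field)
  se <- .edge_sigma
  rc <- max(radius - sqrt(2 * log(2)) * se, 0.5)
  w <- ceiling(radius + 4 * se)
  lo <- pmax(floor(center - w), 1)
  hi <- pmin(ceiling(center + w), d)
  if (any(lo > hi)) return(field)
  iz <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; ix <- lo[3]:hi[3]
  d2 <- outer(outer((iz - center[1])^2, (iy - center[2])^2, "+"),
              (ix - center[3])^2, "+")
  excess <- pmax(sqrt(d2) - rc, 0)
  field[iz, iy, ix] <- pmax(field[iz, iy, ix, drop = FALSE],
                            intensity * exp(-excess^2 / (2 * se^2)))
  field
}

#' Generate a curved vessel tube
#'
#' A smooth random curve (cubic spline through jittered control points,
#' spanning the volume along the x axis) dilated to a tube of the given
#' nominal radius with a Gaussian cross-section profile: intensity 1 on
#' the axis, 0.5 at the nominal radius.
#'
#' @param shape volume dimensions (z, y, x).
#' @param radius nominal tube radius in voxels (>= 1).
#' @param seed integer seed; identical seeds give identical fields.
#' @param n_ctrl number of spline control points.
#' @param jitter control-point jitter as a fraction of the cross-axis size.
#' @return List with `field` (3D array) and `centerline` (matrix of
#'   (z, y, x) sample points).
#' @export
make_vessel <- function(shape, radius, seed = 1L, n_ctrl = 4L, jitter = 0.22) {
  if (radius < 1) stop("radius must be at least 1 voxel")
  margin <- radius + 3
  if (2 * margin >= min(shape)) stop("radius too large for the volume shape")
  withr::with_seed(seed, {
    cx <- seq(1, shape[3], length.out = n_ctrl)
    cz <- shape[1] / 2 + runif(n_ctrl, -jitter, jitter) * shape[1]
    cy <- shape[2] / 2 + runif(n_ctrl, -jitter, jitter) * shape[2]
    xs <- seq(1, shape[3], by = 0.6)
    zf <- pmin(pmax(spline(cx, cz, xout = xs)$y, margin), shape[1] - margin + 1)
    yf <- pmin(pmax(spline(cx, cy, xout = xs)$y, margin), shape[2] - margin + 1)
    centerline <- cbind(z = zf, y = yf, x = xs)
    field <- array(0, shape)
    for (i in seq_len(nrow(centerline)))
      field <- .stamp_ball(field, centerline[i, ], radius)
    list(field = field, centerline = centerline, radius = radius)
  })
}

#' Attach a spherical aneurysm to a vessel
#'
#' Places a soft-edged sphere of the given nominal radius tangent to a
#' randomly chosen centerline point: the sphere center sits at distance
#' `vessel_radius + radius` from that point, along a random direction
#' perpendicular to the local vessel tangent. The sphere is union-max
#' composited into the field. Placement retries (new point, new
#' direction) until the sphere fits inside the volume and respects the
#' separation constraint; after `max_tries` failures an error is raised.
#'
#' @param field 3D intensity array to composite into.
#' @param centerline matrix of vessel centerline points (z, y, x).
#' @param radius nominal aneurysm radius in voxels.
#' @param seed integer seed.
#' @param vessel_radius nominal radius of the parent vessel.
#' @param intensity peak intensity of the sphere.
#' @param existing list of previously placed truth records, used for the
#'   separation constraint.
#' @param min_separation minimum center-to-center distance to previously
#'   placed aneurysms, in voxels (distinct aneurysms sit on distinct
#'   arterial segments).
#' @param max_tries placement attempts before giving up.
#' @return List with `field` (updated array) and `truth` (list with
#'   `center`, `radius`, `vessel`).
#' @export
add_aneurysm <- function(field, centerline, radius, seed = 1L, vessel_radius = 3,
                         intensity = 1, existing = list(), min_separation = 24,
                         max_tries = 100L) {
  d <- dim(field)
  margin <- radius + 2
  withr::with_seed(seed, {
    for (try in seq_len(max_tries)) {
      i <- sample(2:(nrow(centerline) - 1), 1)
      p <- centerline[i, ]
      tangent <- centerline[i + 1, ] - centerline[i - 1, ]
      tangent <- tangent / sqrt(sum(tangent^2))
      v <- rnorm(3)
      v <- v - sum(v * tangent) * tangent
      nv <- sqrt(sum(v^2))
      if (nv < 1e-8) next
      center <- p + (v / nv) * (vessel_radius + radius)
      if (any(center < 1 + margin) || any(center > d - margin)) next
      if (length(existing) > 0) {
        seps <- vapply(existing, function(tr) sqrt(sum((tr$center - center)^2)), 0)
        if (min(seps) < min_separation) next
      }
      field <- .stamp_ball(field, center, radius, intensity)
      return(list(field = field,
                  truth = list(center = center, radius = radius, vessel = 1L)))
    }
    stop("no valid aneurysm placement found after ", max_tries, " tries")
  })
}

#' Phantom specification
#'
#' Study conditions for one synthetic angiography volume. Defaults mirror
#' clinical 3D-DSA structure at 0.5 mm voxels: a 96^3 field of view, one
#' curved vessel of 2-4 voxel radius, aneurysms of 3-8 voxel radius
#' (1.5-4 mm), equal vessel/aneurysm peak contrast, and mild additive
#' Gaussian noise (sd 0.02 of the dynamic range, subtraction angiography
#' being high-contrast).
#'
#' @param shape volume dimensions (z, y, x).
#' @param n_vessels number of vessels.
#' @param vessel_radius_range range the vessel radius is drawn from.
#' @param n_aneurysms number of aneurysms (0-3).
#' @param aneurysm_radius_range range aneurysm radii are drawn from.
#' @param vessel_intensity,aneurysm_intensity peak intensities.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param min_separation minimum aneurysm center separation, voxels.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return List of class `aneuscan_phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96, 96, 96), n_vessels = 1L,
                         vessel_radius_range = c(2, 4), n_aneurysms = 1L,
                         aneurysm_radius_range = c(3, 8),
                         vessel_intensity = 1, aneurysm_intensity = 1,
                         noise_sd = 0.02, min_separation = 24, seed = 1L) {
  if (n_vessels < 0 || n_aneurysms < 0) stop("counts must be >= 0")
  structure(list(shape = shape, n_vessels = as.integer(n_vessels),
                 vessel_radius_range = vessel_radius_range,
                 n_aneurysms = as.integer(n_aneurysms),
                 aneurysm_radius_range = aneurysm_radius_range,
                 vessel_intensity = vessel_intensity,
                 aneurysm_intensity = aneurysm_intensity,
                 noise_sd = noise_sd, min_separation = min_separation,
                 seed = as.integer(seed)),
            class = "aneuscan_phantom_spec")
}

#' Generate a synthetic angiography phantom
#'
#' Composites the specified vessels and attached aneurysms (union-max),
#' adds Gaussian noise, clips to `[0, 1]`, and returns the volume together
#' with the ground-truth aneurysm records.
#'
#' @param spec an [phantom_spec()].
#' @return List with `volume` (an [as_volume()]) and `truth` (list of
#'   records with `center`, `radius`, `vessel`), of length
#'   `spec$n_aneurysms`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "aneuscan_phantom_spec"))
  if (spec$n_aneurysms > 0 && spec$n_vessels < 1)
    stop("aneurysms need at least one vessel to attach to")
  withr::with_seed(spec$seed, {
    sub_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_vessels + spec$n_aneurysms)
    vr <- runif(max(spec$n_vessels, 1), spec$vessel_radius_range[1], spec$vessel_radius_range[2])
    ar <- if (spec$n_aneurysms > 0)
      runif(spec$n_aneurysms, spec$aneurysm_radius_range[1], spec$aneurysm_radius_range[2])
    else numeric()
    parent <- if (spec$n_aneurysms > 0) sample.int(max(spec$n_vessels, 1),
                                                   spec$n_aneurysms, replace = TRUE)
    else integer()
    noise_seed <- sample.int(.Machine$integer.max - 1L, 1)
  })
  field <- array(0, spec$shape)
  vessels <- list()
  for (i in seq_len(spec$n_vessels)) {
    v <- make_vessel(spec$shape, vr[i], seed = sub_seeds[i])
    vessels[[i]] <- v
    field <- pmax(field, spec$vessel_intensity * v$field)
  }
  truth <- list()
  for (j in seq_len(spec$n_aneurysms)) {
    pv <- vessels[[parent[j]]]
    res <- add_aneurysm(field, pv$centerline, ar[j],
                        seed = sub_seeds[spec$n_vessels + j],
                        vessel_radius = pv$radius,
                        intensity = spec$aneurysm_intensity,
                        existing = truth, min_separation = spec$min_separation)
    field <- res$field
    res$truth$vessel <- parent[j]
    truth[[j]] <- res$truth
  }
  if (spec$noise_sd > 0) {
    noise <- withr::with_seed(noise_seed,
                              array(rnorm(length(field), 0, spec$noise_sd), spec$shape))
    field <- field + noise
  }
  field[field < 0] <- 0
  field[field > 1] <- 1
  list(volume = as_volume(field), truth = truth)
}
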