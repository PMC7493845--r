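# Aneurysm extraction: region growth from the response peak, V_max/V_mean
# statistics, adaptive-threshold classification, sphere removal, and the
# iterative multi-aneurysm detection loop.

#' Region growing from a seed over 26-neighborhoods
#'
#' Breadth-first growth over the 26-connected neighborhood of the seed: a
#' voxel joins the target iff its response is at least
#' `max(alpha * response[seed], floor)`. The result is the 26-connected
#' component of qualifying voxels containing the seed.
#'
#' @param response an `aneuscan_response` (or a 3D numeric array).
#' @param seed voxel index triple (z, y, x), 1-based; typically the
#'   response argmax.
#' @param alpha relative inclusion cutoff in (0, 1].
#' @param floor absolute inclusion floor (>= 0).
#' @return Logical 3D array mask.
#' @export
grow_region <- function(response, seed, alpha = 0.5, floor = 0) {
  vals <- if (inherits(response, "aneuscan_response")) response$values else response
  stopifnot(is.array(vals), length(dim(vals)) == 3L)
  if (length(alpha) != 1L || alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (floor < 0) stop("floor must be non-negative")
  d <- dim(vals)
  seed <- as.integer(seed)
  if (length(seed) != 3L || any(seed < 1L) || any(seed > d))
    stop("seed must be a (z, y, x) index inside the volume")
  sval <- vals[seed[1], seed[2], seed[3]]
  if (sval <= 0) stop("empty target: response at the seed is not positive")
  thr <- max(alpha * sval, floor)
  lin0 <- (seed[1] - 1L) + (seed[2] - 1L) * d[1] + (seed[3] - 1L) * d[1] * d[2]
  array(region_grow_cpp(as.vector(vals), d, lin0, thr), d)
}

#' Response statistics of an extracted target
#'
#' `V_max = max(O)` and `V_mean = mean(O)` with `O` the set of filter
#' response values over the target mask.
#'
#' @param response an `aneuscan_response` (or 3D array).
#' @param mask logical 3D array, non-empty.
#' @return List of class `aneuscan_stats` with `V_max`, `V_mean`, `n_voxels`.
#' @export
target_stats <- function(response, mask) {
  vals <- if (inherits(response, "aneuscan_response")) response$values else response
  if (!any(mask)) stop("empty mask")
  o <- vals[mask]
  structure(list(V_max = max(o), V_mean = mean(o), n_voxels = length(o)),
            class = "aneuscan_stats")
}

#' Adaptive-threshold classification of a target
#'
#' The target is an aneurysm iff the selected response statistic (mean or
#' maximum) strictly exceeds the threshold. The mean is the preferred
#' statistic: the filter response over an aneurysm is uniform, while
#' vascular protrusions can carry isolated response maxima.
#'
#' @param stats an `aneuscan_stats` from [target_stats()].
#' @param mode `"mean"` (use `V_mean`) or `"max"` (use `V_max`).
#' @param threshold decision threshold.
#' @return Logical.
#' @export
classify_target <- function(stats, mode = c("mean", "max"), threshold) {
  mode <- match.arg(mode)
  stat <- if (mode == "mean") stats$V_mean else stats$V_max
  stat > threshold
}

#' Removal sphere of a target mask
#'
#' Center of mass of the mask plus a radius set to the maximum of the
#' target's axis-aligned bounding-box extents (length, width, height in
#' voxels) -- the printed extraction rule. `convention = "half_extent"`
#' uses half that value instead.
#'
#' @param mask logical 3D array, non-empty.
#' @param convention `"extent"` (default, radius = max extent) or
#'   `"half_extent"`.
#' @return List with `center` (real (z, y, x) triple) and `radius`.
#' @export
removal_sphere <- function(mask, convention = c("extent", "half_extent")) {
  convention <- match.arg(convention)
  if (!any(mask)) stop("empty mask")
  idx <- which(mask)
  coords <- arrayInd(idx, dim(mask))
  center <- colMeans(coords)
  extents <- apply(coords, 2, function(v) diff(range(v)) + 1)
  r <- max(extents)
  if (convention == "half_extent") r <- r / 2
  list(center = center, radius = r)
}

#' Remove a spherical region from a volume
#'
#' Sets all voxels within Euclidean distance `radius` (in voxels) of
#' `center` to zero, leaving every other voxel untouched.
#'
#' @param volume an [as_volume()] object.
#' @param center real (z, y, x) triple.
#' @param radius positive radius in voxels.
#' @return The modified [as_volume()] object.
#' @export
remove_target <- function(volume, center, radius) {
  stopifnot(is_volume(volume))
  if (radius <= 0) stop("radius must be positive")
  d <- dim(volume$data)
  lo <- pmax(floor(center - radius), 1)
  hi <- pmin(ceiling(center + radius), d)
  if (any(lo > hi)) return(volume)
  iz <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; ix <- lo[3]:hi[3]
  d2 <- outer(outer((iz - center[1])^2, (iy - center[2])^2, "+"),
              (ix - center[3])^2, "+")
  sub <- volume$data[iz, iy, ix, drop = FALSE]
  sub[d2 <= radius^2] <- 0
  volume$data[iz, iy, ix] <- sub
  volume
}

#' Detection configuration
#'
#' Knobs of the full iterative detection pipeline.
#'
#' @param threshold classification threshold on the selected response
#'   statistic. The deployment value should be calibrated on data with
#'   known ground truth (see [run_benchmark()]); the default is only a
#'   mid-scale placeholder.
#' @param mode classification statistic, `"mean"` or `"max"`.
#' @param alpha relative region-growth cutoff.
#' @param floor absolute region-growth floor.
#' @param bo_budget objective evaluations per detection round.
#' @param n_init initial design size inside the budget.
#' @param seed master seed; round `r` uses `seed + r`.
#' @param bounds search box for (s, tau).
#' @param t_sigma exploration ratio of the overexploitation rule.
#' @param max_rounds hard cap on detection rounds.
#' @param removal removal-sphere convention, see [removal_sphere()].
#' @param median_window preprocessing median window (0 skips).
#' @param variant filter variant, see [blobness()].
#' @param harvest if TRUE, every extracted target is removed and the loop
#'   runs to `max_rounds` regardless of classification (used to collect
#'   candidate targets for threshold sweeps); detections still contain
#'   only the targets classified as aneurysms.
#' @return List of class `aneuscan_config`.
#' @export
detect_config <- function(threshold = 0.5, mode = c("mean", "max"), alpha = 0.5,
                          floor = 0, bo_budget = 50L, n_init = 4L, seed = 1L,
                          bounds = default_bounds(), t_sigma = 0.5,
                          max_rounds = 5L, removal = c("extent", "half_extent"),
                          median_window = 3L, variant = c("printed", "jerman"),
                          harvest = FALSE) {
  structure(list(threshold = threshold, mode = match.arg(mode), alpha = alpha,
                 floor = floor, bo_budget = as.integer(bo_budget),
                 n_init = as.integer(n_init), seed = as.integer(seed),
                 bounds = .check_bounds(bounds), t_sigma = t_sigma,
                 max_rounds = as.integer(max_rounds),
                 removal = match.arg(removal),
                 median_window = as.integer(median_window),
                 variant = match.arg(variant), harvest = isTRUE(harvest)),
            class = "aneuscan_config")
}

#' Iterative aneurysm detection
#'
#' The full pipeline: preprocess once (median denoise + 0-1
#' normalization); then per round, optimize the reciprocal-response loss
#' over (s, tau) by Bayesian optimization, build the response at the
#' optimum, seed region growth at the response argmax, compute
#' `V_max`/`V_mean`, classify; if the target is an aneurysm, record it,
#' remove its sphere from the working volume and continue with a fresh
#' parameter search, else stop. Each round therefore gets its own optimal
#' parameter pair. The loop also stops at `max_rounds` or when the
#' working volume carries no response.
#'
#' @param volume a raw [as_volume()] object.
#' @param config an [detect_config()].
#' @return Object of class `aneuscan_detections`: list with `detections`
#'   (targets classified as aneurysms), `candidates` (every extracted
#'   target, in round order -- identical to `detections` up to the first
#'   rejection unless `harvest`), `rounds`, `config` and `volume`
#'   (preprocessed working volume after all removals). Each detection
#'   holds `round`, `params`, `seed_voxel`, `voxels` (linear indices),
#'   `centroid`, `removal_radius`, `V_max`, `V_mean`, `is_aneurysm`,
#'   `bo_trace`.
#' @export
detect_aneurysms <- function(volume, config = detect_config()) {
  stopifnot(is_volume(volume), inherits(config, "aneuscan_config"))
  if (diff(range(volume$data)) == 0) {
    message("empty or constant volume: no detection possible")
    return(structure(list(detections = list(), candidates = list(), rounds = 0L,
                          config = config, volume = volume),
                     class = "aneuscan_detections"))
  }
  work <- suppressWarnings(preprocess_volume(volume, config$median_window))
  detections <- list()
  candidates <- list()
  round_i <- 0L
  while (round_i < config$max_rounds) {
    round_i <- round_i + 1L
    if (max(work$data) <= 0) { round_i <- round_i - 1L; break }
    loss <- reciprocal_loss(work, variant = config$variant)
    opt <- bayes_optimize(loss, bounds = config$bounds, budget = config$bo_budget,
                          seed = config$seed + round_i, n_init = config$n_init,
                          t_sigma = config$t_sigma)
    resp <- filter_response(work, opt$best, variant = config$variant)
    if (max(resp$values) <= 0) { round_i <- round_i - 1L; break }
    seed_vox <- arrayInd(which.max(resp$values), dim(resp$values))[1, ]
    mask <- grow_region(resp, seed_vox, alpha = config$alpha, floor = config$floor)
    st <- target_stats(resp, mask)
    sph <- removal_sphere(mask, convention = config$removal)
    is_an <- classify_target(st, mode = config$mode, threshold = config$threshold)
    det <- list(round = round_i, params = opt$best, seed_voxel = seed_vox,
                voxels = which(mask), centroid = sph$center,
                removal_radius = sph$radius, V_max = st$V_max, V_mean = st$V_mean,
                is_aneurysm = is_an, bo_trace = opt$trace)
    candidates[[length(candidates) + 1L]] <- det
    if (is_an) detections[[length(detections) + 1L]] <- det
    if (is_an || config$harvest) {
      work <- remove_target(work, sph$center, sph$radius)
    } else break
  }
  structure(list(detections = detections, candidates = candidates,
                 rounds = round_i, config = config, volume = work),
            class = "aneuscan_detections")
}

#' @export
print.aneuscan_detections <- function(x, ...) {
  cat(sprintf("<aneuscan_detections> %d aneurysm(s) in %d round(s)\n",
              length(x$detections), x$rounds))
  for (d in x$candidates)
    cat(sprintf("  round %d: s=%.2f tau=%.3f centroid=(%.1f, %.1f, %.1f) V_mean=%.4g V_max=%.4g %s\n",
                d$round, d$params$s, d$params$tau, d$centroid[1], d$centroid[2],
                d$centroid[3], d$V_mean, d$V_max,
                if (d$is_aneurysm) "ANEURYSM" else "rejected"))
  invisible(x)
}

#' Detections as a data frame
#'
#' @param x an `aneuscan_detections` object.
#' @param candidates if TRUE, tabulate all extracted candidates rather
#'   than only accepted detections.
#' @return data.frame with one row per target.
#' @export
detections_df <- function(x, candidates = FALSE) {
  src <- if (candidates) x$candidates else x$detections
  if (length(src) == 0)
    return(data.frame(round = integer(), s = numeric(), tau = numeric(),
                      z = numeric(), y = numeric(), xpos = numeric(),
                      n_voxels = integer(), removal_radius = numeric(),
                      V_max = numeric(), V_mean = numeric(),
                      is_aneurysm = logical()))
  do.call(rbind, lapply(src, function(d) data.frame(
    round = d$round, s = d$params$s, tau = d$params$tau,
    z = d$centroid[1], y = d$centroid[2], xpos = d$centroid[3],
    n_voxels = length(d$voxels), removal_radius = d$removal_radius,
    V_max = d$V_max, V_mean = d$V_mean, is_aneurysm = d$is_aneurysm)))
}

#' Label mask of accepted detections
#'
#' @param x an `aneuscan_detections` object.
#' @param dim volume dimensions (z, y, x).
#' @return Integer 3D array: 0 background, k for the k-th detection.
#' @export
detections_label_mask <- function(x, dim) {
  lab <- array(0L, dim)
  for (i in seq_along(x$detections)) lab[x$detections[[i]]$voxels] <- i
  lab
}
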