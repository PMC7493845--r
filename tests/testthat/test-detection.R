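# Region growth, target statistics, classification, removal, and the
# iterative detection loop.

test_that("region growth handles points, plateaus, and matches flood fill", {
  d <- c(9, 9, 9)
  single <- array(0, d); single[5, 5, 5] <- 1
  m <- grow_region(single, c(5, 5, 5))
  expect_identical(sum(m), 1L)
  expect_true(m[5, 5, 5])
  # uniform 5^3 plateau: everything above half the seed value joins
  cube <- array(0, d); cube[3:7, 3:7, 3:7] <- 1
  mc <- grow_region(cube, c(5, 5, 5), alpha = 0.5)
  expect_identical(sum(mc), 125L)
  expect_true(all(which(mc) %in% which(cube == 1)))
  # flood-fill oracle on smooth random fields
  for (seed in 1:5) {
    vals <- smooth_random_volume(n = 12, seed = seed)
    peak <- arrayInd(which.max(vals), dim(vals))[1, ]
    got <- grow_region(vals, peak, alpha = 0.6)
    want <- slow_flood_fill(vals, peak, 0.6 * vals[peak[1], peak[2], peak[3]])
    expect_identical(got, want)
  }
  expect_error(grow_region(array(0, d), c(1, 1, 1)), "empty target")
  expect_error(grow_region(single, c(99, 1, 1)), "inside")
})

test_that("target statistics are the mask max and mean", {
  vals <- array(0, c(5, 5, 5))
  vals[1, 1, 1] <- 0.7
  m1 <- array(FALSE, c(5, 5, 5)); m1[1, 1, 1] <- TRUE
  s1 <- target_stats(vals, m1)
  expect_equal(s1$V_max, 0.7); expect_equal(s1$V_mean, 0.7)
  vals[1:3, 2, 2] <- c(1, 2, 3)
  m2 <- array(FALSE, c(5, 5, 5)); m2[1:3, 2, 2] <- TRUE
  s2 <- target_stats(vals, m2)
  expect_equal(s2$V_max, 3); expect_equal(s2$V_mean, 2)
  expect_error(target_stats(vals, array(FALSE, c(5, 5, 5))), "empty")
  # random mask vs explicit loop
  withr::with_seed(3, {
    v <- array(runif(6^3), c(6, 6, 6))
    mk <- array(runif(6^3) > 0.7, c(6, 6, 6))
    st <- target_stats(v, mk)
    acc <- c()
    for (i in 1:6) for (j in 1:6) for (k in 1:6)
      if (mk[i, j, k]) acc <- c(acc, v[i, j, k])
    expect_equal(st$V_max, max(acc))
    expect_equal(st$V_mean, mean(acc))
  })
})

test_that("classification is strict and flips exactly once over a sweep", {
  st <- structure(list(V_max = 0.9, V_mean = 0.6), class = "aneuscan_stats")
  expect_true(classify_target(st, "mean", 0.5))
  expect_false(classify_target(st, "mean", 0.6))   # tie -> not an aneurysm
  expect_true(classify_target(st, "max", 0.85))
  expect_error(classify_target(st, "median", 0.5), "arg")
  sweep <- seq(1.0, 0.1, by = -0.05)
  dec <- vapply(sweep, function(t) classify_target(st, "mean", t), TRUE)
  expect_identical(sum(diff(dec) != 0), 1L)
})

test_that("removal sphere uses the center of mass and max bbox extent", {
  m <- array(FALSE, c(10, 10, 10)); m[4, 5, 6] <- TRUE
  s <- removal_sphere(m)
  expect_equal(s$center, c(4, 5, 6), ignore_attr = TRUE)
  expect_equal(s$radius, 1)
  box <- array(FALSE, c(12, 12, 12)); box[2:4, 3:7, 5:11] <- TRUE
  sb <- removal_sphere(box)
  expect_equal(sb$radius, 7)           # extents 3 x 5 x 7
  expect_equal(sb$center, c(3, 5, 8), ignore_attr = TRUE)
  expect_equal(removal_sphere(box, "half_extent")$radius, 3.5)
  # accumulation oracle on a random blob
  withr::with_seed(9, {
    mk <- array(runif(8^3) > 0.6, c(8, 8, 8))
    sr <- removal_sphere(mk)
    acc <- matrix(0, 0, 3)
    for (i in 1:8) for (j in 1:8) for (k in 1:8)
      if (mk[i, j, k]) acc <- rbind(acc, c(i, j, k))
    expect_equal(sr$center, colMeans(acc), ignore_attr = TRUE)
    expect_equal(sr$radius, max(apply(acc, 2, function(v) diff(range(v)) + 1)))
  })
})

test_that("sphere removal zeroes exactly the in-radius voxels", {
  v <- as_volume(array(1, c(9, 9, 9)))
  tiny <- remove_target(v, c(5, 5, 5), 0.4)
  expect_lte(sum(tiny$data == 0), 1)
  all_gone <- remove_target(v, c(5, 5, 5), 20)
  expect_true(all(all_gone$data == 0))
  # lattice-sphere count: zeroed voxels approximate (4/3) pi r^3
  big <- as_volume(array(1, c(31, 31, 31)))
  r6 <- remove_target(big, c(16, 16, 16), 6)
  n_zero <- sum(r6$data == 0)
  expect_lt(abs(n_zero - 4 / 3 * pi * 6^3) / (4 / 3 * pi * 6^3), 0.15)
  # untouched voxels are bit-identical
  expect_true(all(r6$data %in% c(0, 1)))
  expect_error(remove_target(v, c(5, 5, 5), 0), "positive")
})

test_that("detector finds a planted sphere on a vessel", {
  ph <- generate_phantom(phantom_spec(shape = c(64, 64, 64), n_aneurysms = 1,
                                      aneurysm_radius_range = c(4, 4), seed = 21))
  # threshold between the planted sphere's V_mean (~0.62) and the next
  # candidate's (~0.39): accept the aneurysm, reject the follow-up, stop
  cfg <- detect_config(threshold = 0.5, bo_budget = 14, seed = 1, max_rounds = 3)
  res <- detect_aneurysms(ph$volume, cfg)
  expect_identical(length(res$detections), 1L)
  d <- res$detections[[1]]
  expect_lte(sqrt(sum((d$centroid - ph$truth[[1]]$center)^2)), 2)
  expect_true(d$is_aneurysm)
  expect_lte(d$V_mean, d$V_max)
  # the detection mask contains the seed and the BO trace spans the budget
  expect_true(d$seed_voxel[1] >= 1)
  seed_lin <- d$seed_voxel[1] + (d$seed_voxel[2] - 1) * 64 +
    (d$seed_voxel[3] - 1) * 64^2
  expect_true(seed_lin %in% d$voxels)
  expect_identical(nrow(d$bo_trace), 14L)
})

test_that("detector extracts two aneurysms in two rounds then stops", {
  ph <- generate_phantom(phantom_spec(shape = c(72, 72, 72), n_aneurysms = 2,
                                      aneurysm_radius_range = c(4, 6), seed = 31))
  # threshold below both aneurysms' V_mean (~0.67, ~0.64) and above the
  # third candidate's (~0.53)
  cfg <- detect_config(threshold = 0.55, bo_budget = 14, seed = 2, max_rounds = 4)
  res <- detect_aneurysms(ph$volume, cfg)
  expect_identical(length(res$detections), 2L)
  conf <- match_detections(res$detections, ph$truth, slack = 2)
  expect_identical(conf$TP, 2L)
  # each round used its own optimized parameter pair
  expect_false(isTRUE(all.equal(res$detections[[1]]$params$s,
                                res$detections[[2]]$params$s)))
  # masks of later rounds are disjoint from earlier removals
  expect_length(intersect(res$detections[[1]]$voxels,
                          res$detections[[2]]$voxels), 0)
  # loop terminated on a rejection or round cap
  expect_lte(res$rounds, 4L)
})

test_that("degenerate volumes yield empty detection lists", {
  expect_message(res <- detect_aneurysms(as_volume(array(0, c(16, 16, 16))),
                                         detect_config(bo_budget = 5)),
                 "constant")
  expect_identical(length(res$detections), 0L)
  expect_identical(res$rounds, 0L)
})
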