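# Skeleton- and area-based morphometry against closed-form shapes,
# brute-force oracles, and generator ground truth.

test_that("skeleton of elongated and blob shapes behaves as a medial axis", {
  # 9-px-wide, 100-px-long bar: one path along the mid-row
  sk <- skeletonize_mask(bar_mask())
  expect_identical(length(sk$junctions), 0L)
  expect_identical(length(sk$segments), 1L)
  px <- which(sk$skeleton, arr.ind = TRUE)
  interior <- px[px[, 2] > 25 & px[, 2] < 95, , drop = FALSE]
  expect_true(all(interior[, 1] == 20))
  # skeleton is always a subset of the foreground
  expect_true(all(bar_mask()[sk$skeleton]))

  # a filled disk has no elongation: skeleton collapses to a few pixels
  m <- matrix(FALSE, 41, 41)
  for (r in 1:41) for (c in 1:41) m[r, c] <- (r - 21)^2 + (c - 21)^2 <= 15^2
  skd <- skeletonize_mask(m)
  expect_lte(sum(skd$skeleton), 5)
  expect_identical(length(skd$junctions), 0L)

  # empty mask: valid empty skeleton
  sk0 <- skeletonize_mask(matrix(FALSE, 10, 10))
  expect_identical(sum(sk0$skeleton), 0L)
  expect_identical(count_vessels(sk0), 0L)
  expect_identical(total_length(sk0), 0)
})

test_that("branch points and vessels count junction clusters and arms", {
  skc <- skeletonize_mask(cross_mask(), prune_spurs_px = 0)
  expect_identical(count_branch_points(skc), 1L)
  expect_identical(count_vessels(skc), 4L)

  skt <- skeletonize_mask(tee_mask(), prune_spurs_px = 0)
  expect_identical(count_branch_points(skt), 1L)
  expect_identical(count_vessels(skt), 3L)

  line <- matrix(FALSE, 9, 60); line[5, 6:55] <- TRUE
  skl <- skeletonize_mask(line)
  expect_identical(count_branch_points(skl), 0L)
  expect_identical(count_vessels(skl), 1L)

  # rendered full binary tree with 3 levels recovers 7 branch points and
  # 2^4 - 1 = 15 vessels
  smp <- default_sample(seed = 1)
  sk <- skeletonize_mask(smp$truth_mask)
  expect_identical(count_branch_points(sk), smp$truth$n_branch_points)
  expect_identical(count_branch_points(sk), 7L)
  expect_identical(count_vessels(sk), 15L)
})

test_that("total length sums unit and diagonal steps", {
  line <- matrix(FALSE, 9, 60); line[5, 6:55] <- TRUE
  expect_equal(total_length(skeletonize_mask(line)), 49)

  diag50 <- matrix(FALSE, 60, 60)
  for (i in 1:50) diag50[i + 4, i + 4] <- TRUE
  expect_equal(total_length(skeletonize_mask(diag50)), 49 * sqrt(2))

  # rendered tree: within 5% of the generator's chord-length truth
  smp <- default_sample(seed = 2)
  sk <- skeletonize_mask(smp$truth_mask)
  expect_lt(abs(total_length(sk) / smp$truth$total_length_px - 1), 0.05)
})

test_that("mean thickness follows the 2 * EDT - 1 convention", {
  expect_equal(mean_thickness(skeletonize_mask(bar_mask(width = 9))), 9,
               tolerance = 0.5 / 9)

  # two bars of widths 5 and 9 with equal skeleton lengths average ~7
  m <- bar_mask(h = 60, row_center = 15, width = 5) |
    bar_mask(h = 60, row_center = 45, width = 9)
  expect_equal(mean_thickness(skeletonize_mask(m)), 7, tolerance = 0.06)

  # 1-px line: radius 1 under the pixel-center convention
  line <- matrix(FALSE, 9, 60); line[5, 6:55] <- TRUE
  expect_equal(mean_thickness(skeletonize_mask(line)), 1)

  expect_error(mean_thickness(skeletonize_mask(matrix(FALSE, 5, 5))),
               class = "camq_undefined_metric")
})

test_that("total area counts foreground pixels", {
  m <- matrix(FALSE, 20, 20); m[6:15, 6:15] <- TRUE
  expect_identical(total_area(m), 100L)
  expect_identical(total_area(matrix(FALSE, 7, 7)), 0L)
  smp <- default_sample(seed = 3)
  expect_identical(total_area(smp$truth_mask), smp$truth$mask_area_px2)
})

test_that("gliding-box lacunarity matches closed forms and enumeration", {
  # uniform coverage: zero variance at every scale
  all_fg <- matrix(TRUE, 16, 16)
  lac <- lacunarity(all_fg, c(1, 2, 4))
  expect_equal(lac$lacunarity, rep(1, 3))

  # half-plane at r = 1: Bernoulli(1/2) mass, var/mean^2 + 1 = 2
  half <- matrix(FALSE, 32, 32); half[1:16, ] <- TRUE
  expect_equal(lacunarity(half, 1)$lacunarity, 2)

  # random mask vs exhaustive window enumeration
  m <- random_blob_mask(32, 32, seed = 4, frac = 0.4)
  lc <- lacunarity(m, c(2, 4))
  expect_equal(lc$lacunarity[1], oracle_lacunarity(m, 2), tolerance = 1e-9)
  expect_equal(lc$lacunarity[2], oracle_lacunarity(m, 4), tolerance = 1e-9)

  expect_error(lacunarity(matrix(FALSE, 8, 8), 2),
               class = "camq_undefined_metric")
  expect_error(lacunarity(matrix(TRUE, 8, 8), 16), "box sizes")
})

test_that("the aggregated report equals the individually computed metrics", {
  smp <- default_sample(seed = 4)
  rep <- morphometry_report(smp$truth_mask)
  sk <- skeletonize_mask(smp$truth_mask)
  expect_identical(rep$total_area_px2, total_area(smp$truth_mask))
  expect_identical(rep$n_branch_points, count_branch_points(sk))
  expect_identical(rep$n_vessels, count_vessels(sk))
  expect_equal(rep$total_length_px, total_length(sk))
  expect_equal(rep$mean_thickness_px, mean_thickness(sk))
  expect_equal(rep$vessel_density, sum(smp$truth_mask) / prod(dim(smp$truth_mask)))
  expect_identical(rep$n_components, 1L)
  expect_gte(rep$n_junction_pixels, rep$n_branch_points)

  # empty mask: zeros and flagged undefined metrics
  rep0 <- morphometry_report(matrix(FALSE, 30, 30))
  expect_identical(rep0$total_area_px2, 0L)
  expect_identical(rep0$n_branch_points, 0L)
  expect_true(is.na(rep0$mean_thickness_px))
  expect_true(is.na(rep0$lacunarity))
})

test_that("skeleton metrics match brute-force enumeration on fixed shapes", {
  for (mask in list(cross_mask(), tee_mask(), bar_mask(),
                    random_blob_mask(48, 48, seed = 7))) {
    sk <- skeletonize_mask(mask)
    o <- oracle_skeleton_metrics(sk$skeleton)
    expect_identical(count_branch_points(sk), o$n_branch_points)
    expect_identical(count_vessels(sk), o$n_segments)
    expect_equal(total_length(sk), o$total_length, tolerance = 1e-12)
  }
})

test_that("scalar metrics are invariant to rotation and mirroring", {
  smp <- default_sample(seed = 6, image_height_px = 200, image_width_px = 200)
  m <- smp$truth_mask
  variants <- list(m,
                   t(m)[ncol(m):1, ],          # 90 degree rotation
                   m[, ncol(m):1])             # mirror
  reps <- lapply(variants, function(v) skeletonize_mask(v))
  bp <- vapply(reps, count_branch_points, 0L)
  ln <- vapply(reps, total_length, 0)
  ar <- vapply(variants, total_area, 0L)
  expect_true(all(bp == bp[1]))
  expect_equal(ln, rep(ln[1], 3))
  expect_true(all(ar == ar[1]))
})

test_that("adding a disjoint vessel strictly increases area and length", {
  smp <- default_sample(seed = 7, image_height_px = 200, image_width_px = 260)
  m <- smp$truth_mask
  extra <- matrix(FALSE, nrow(m), ncol(m))
  extra[2:6, 240:258] <- TRUE            # far corner, disjoint bar
  stopifnot(!any(m & extra))
  m2 <- m | extra
  expect_gt(total_area(m2), total_area(m))
  expect_gt(total_length(skeletonize_mask(m2)), total_length(skeletonize_mask(m)))
})
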