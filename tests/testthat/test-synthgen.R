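# Synthetic vascular network generator: topology, determinism,
# rendering contract, artifact injection.

test_that("tree topology matches the bifurcation level", {
  # no bifurcation: a single root-to-tip segment
  p0 <- generator_params(bifurcation_levels = 0, seed = 3)
  net0 <- generate_network(p0)
  expect_length(net0$segments, 1)
  expect_setequal(net0$nodes$kind, c("root", "tip"))
  expect_identical(network_truth(net0)$n_branch_points, 0L)

  # three levels, unclipped: a full binary tree has 2^3 - 1 = 7 branch
  # nodes and 2^4 - 1 = 15 segments
  p3 <- generator_params(bifurcation_levels = 3, seed = 1)
  net3 <- generate_network(p3)
  truth <- network_truth(net3)
  expect_identical(truth$n_branch_points, 7L)
  expect_length(net3$segments, 15)
  # every branch node has degree >= 3
  deg <- table(factor(c(vapply(net3$segments, `[[`, 0L, "from"),
                        vapply(net3$segments, `[[`, 0L, "to")),
                      levels = net3$nodes$id))
  expect_true(all(deg[net3$nodes$kind == "branch"] >= 3))
})

test_that("generation is deterministic for a fixed seed", {
  p <- generator_params(seed = 11)
  expect_identical(generate_network(p), generate_network(p))
  s1 <- render_network(generate_network(p), p)
  s2 <- render_network(generate_network(p), p)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$truth_mask, s2$truth_mask)
  # different seeds give different networks
  p2 <- generator_params(seed = 12)
  expect_false(identical(generate_network(p), generate_network(p2)))
})

test_that("ground-truth length equals the summed polyline chords", {
  net <- generate_network(generator_params(seed = 5))
  manual <- sum(vapply(net$segments, function(sg)
    sum(sqrt(rowSums(diff(sg$polyline)^2))), 0))
  expect_equal(network_truth(net)$total_length_px, manual, tolerance = 1e-12)
})

test_that("deeper bifurcation strictly increases branch points and length", {
  for (s in c(1, 2)) {
    t2 <- network_truth(generate_network(generator_params(seed = s, bifurcation_levels = 2)))
    t3 <- network_truth(generate_network(generator_params(seed = s, bifurcation_levels = 3)))
    expect_gt(t3$n_branch_points, t2$n_branch_points)
    expect_gt(t3$total_length_px, t2$total_length_px)
  }
})

test_that("parameter validation rejects degenerate configurations", {
  expect_error(generator_params(image_height_px = 0), "extent")
  expect_error(generator_params(n_roots = 0), "n_roots")
  expect_error(generator_params(radius_taper = 1.2), "radius_taper")
})

test_that("rendered truth mask follows the pixel-center inclusion rule", {
  # empty network renders an all-background mask
  p <- generator_params(seed = 1, bifurcation_levels = 0,
                        image_height_px = 40, image_width_px = 40)
  empty_net <- structure(list(nodes = tibble::tibble(), segments = list(),
                              params = p), class = "camq_network")
  s <- render_network(empty_net, p)
  expect_identical(sum(s$truth_mask), 0L)
  expect_identical(s$truth$mask_area_px2, 0L)

  # horizontal bar of constant radius 4: 9 px wide by 100 plus end caps
  p2 <- generator_params(seed = 1, image_height_px = 40, image_width_px = 130)
  net <- structure(list(
    nodes = tibble::tibble(id = 1:2, row = c(19, 19), col = c(15, 115),
                           kind = c("root", "tip")),
    segments = list(list(polyline = rbind(c(19, 15), c(19, 115)),
                         radius = c(4, 4), from = 1L, to = 2L, level = 0L)),
    params = p2), class = "camq_network")
  s2 <- render_network(net, p2)
  expect_gte(s2$truth$mask_area_px2, 9 * 101)
  expect_lte(s2$truth$mask_area_px2, 9 * 101 + 60)  # two half-disk caps

  # exact agreement with the brute-force point-to-polyline oracle
  p3 <- generator_params(seed = 9, bifurcation_levels = 1,
                         image_height_px = 60, image_width_px = 60,
                         segment_length_px = c(18, 3), root_radius_px = 3)
  net3 <- generate_network(p3)
  s3 <- render_network(net3, p3)
  expect_identical(s3$truth_mask, oracle_rasterize(net3, 60, 60))
})

test_that("artifacts corrupt the image but never the truth", {
  smp <- default_sample(seed = 21)
  # zero-intensity artifacts are a no-op
  off <- artifact_params(n_highlights = 0, n_deep_vessels = 0)
  s0 <- add_artifacts(smp, off)
  expect_identical(s0$image, smp$image)
  expect_identical(sum(s0$artifact_mask), 0L)

  withart <- add_artifacts(smp, artifact_params())
  # artifact mask records exactly the altered pixels
  changed <- apply(abs(withart$image - smp$image) > 0, c(1, 2), any)
  expect_true(all(changed[!withart$artifact_mask] == FALSE))
  expect_gt(sum(withart$artifact_mask), 0)
  # truth is artifact-independent
  expect_identical(withart$truth_mask, smp$truth_mask)
  expect_identical(withart$truth, smp$truth)

  # highlights brighten: luminance never decreases under highlights only
  hl <- add_artifacts(smp, artifact_params(n_deep_vessels = 0))
  lum0 <- smp$image[, , 1] + smp$image[, , 2] + smp$image[, , 3]
  lum1 <- hl$image[, , 1] + hl$image[, , 2] + hl$image[, , 3]
  expect_true(all(lum1[hl$artifact_mask] >= lum0[hl$artifact_mask]))
})
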