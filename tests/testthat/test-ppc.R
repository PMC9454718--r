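# Positive pixel count: color classification, exclusion regions,
# conservation and monotonicity.

test_that("a uniform stain-colored image is entirely strong positive", {
  img <- flat_image(20, 30, c(0.3, 0.0, 0.0))   # saturated dark red
  r <- classify_pixels(img)
  expect_identical(r$n_strong, 600L)
  expect_identical(r$n_negative, 0L)
  expect_equal(r$strong_positive_pct, 100)

  # excluding half the image halves the counts but not the percentage
  excl <- matrix(FALSE, 20, 30); excl[, 1:15] <- TRUE
  r2 <- classify_pixels(img, exclusion = excl)
  expect_identical(r2$n_strong, 300L)
  expect_identical(r2$n_excluded, 300L)
  expect_equal(r2$strong_positive_pct, 100)

  expect_error(classify_pixels(img, exclusion = matrix(TRUE, 20, 30)),
               class = "camq_undefined_metric")
  expect_error(classify_pixels(img, exclusion = matrix(FALSE, 5, 5)),
               "dimensions")
})

test_that("class counts always conserve the pixel total", {
  for (s in 1:5) {
    img <- withr::with_seed(s, array(runif(40 * 40 * 3), c(40, 40, 3)))
    excl <- withr::with_seed(s + 99, matrix(runif(1600) < 0.2, 40, 40))
    r <- classify_pixels(img, exclusion = excl)
    expect_identical(r$n_strong + r$n_medium + r$n_weak + r$n_negative +
                       r$n_excluded, 1600L)
  }
})

test_that("classification is a pure per-pixel rule", {
  img <- withr::with_seed(1, array(runif(30 * 30 * 3), c(30, 30, 3)))
  perm <- withr::with_seed(2, sample.int(900))
  shuffled <- array(0, dim(img))
  for (k in 1:3) shuffled[, , k] <- matrix(as.vector(img[, , k])[perm], 30, 30)
  r1 <- classify_pixels(img)
  r2 <- classify_pixels(shuffled)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("widening the hue band never loses positives", {
  img <- withr::with_seed(3, array(runif(50 * 50 * 3), c(50, 50, 3)))
  pos <- vapply(c(5, 15, 30, 60, 120, 180), function(wd) {
    r <- classify_pixels(img, ppc_config(hue_width_deg = wd))
    r$n_strong + r$n_medium + r$n_weak
  }, 0L)
  expect_true(all(diff(pos) >= 0))
})

test_that("positive area tracks the rendered vessel area", {
  smp <- default_sample(seed = 7)
  r <- classify_pixels(smp$image)
  pos <- r$n_strong + r$n_medium + r$n_weak
  expect_lt(abs(pos / smp$truth$mask_area_px2 - 1), 0.15)
})

test_that("exclusion sweeps reproduce the artifact failure modes", {
  smp <- default_sample(seed = 11)
  # artifact-free: exclusion changes nothing
  sw0 <- sweep_exclusion_effect(smp)
  expect_identical(sw0$strong_positive_pct_diff, 0)

  # dark-red deeper-vessel artifacts sit inside the positive color
  # range: excluding them removes inflated positives
  dv <- add_artifacts(smp, artifact_params(n_highlights = 0))
  sw <- sweep_exclusion_effect(dv)
  pos_wo <- with(sw$without_exclusion, n_strong + n_medium + n_weak)
  pos_w <- with(sw$with_exclusion, n_strong + n_medium + n_weak)
  expect_lt(pos_w, pos_wo)

  # bright specular highlights are outside the positive range: the
  # strong-positive percentage barely moves
  hl <- add_artifacts(smp, artifact_params(n_deep_vessels = 0))
  sw2 <- sweep_exclusion_effect(hl)
  expect_lt(abs(sw2$strong_positive_pct_diff), 0.1)
})

test_that("ppc config validates threshold ordering", {
  expect_error(ppc_config(isp = 250), "iwp >= imp >= isp")
  expect_error(ppc_config(hue_width_deg = 200), "hue_width_deg")
})
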