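# Bland-Altman limits of agreement and paired t statistics.

test_that("the worked three-pair example reproduces the derived values", {
  ba <- bland_altman(c(10, 20, 30), c(12, 19, 33))
  expect_equal(ba$bias, -4 / 3, tolerance = 1e-12)
  expect_equal(ba$sd_diff, sqrt(13 / 3), tolerance = 1e-12)
  expect_equal(ba$bias, -1.3333, tolerance = 1e-4)
  expect_equal(ba$sd_diff, 2.0817, tolerance = 1e-4)
  expect_equal(ba$loa_low, -5.4135, tolerance = 1e-4)
  expect_equal(ba$loa_high, 2.7468, tolerance = 1e-4)
  expect_equal(ba$t_stat, -1.1094, tolerance = 1e-4)
  expect_identical(ba$df, 2L)
  # independent check of the p-value via R's own t machinery
  tt <- stats::t.test(c(10, 20, 30), c(12, 19, 33), paired = TRUE)
  expect_equal(ba$t_stat, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(ba$p_two_sided, tt$p.value, tolerance = 1e-12)
})

test_that("degenerate difference series are handled as specified", {
  x <- c(3, 1, 4, 1, 5)
  ba <- bland_altman(x, x)
  expect_identical(ba$bias, 0)
  expect_identical(ba$sd_diff, 0)
  expect_identical(c(ba$loa_low, ba$loa_high), c(0, 0))
  expect_true(is.na(ba$t_stat))

  ba2 <- bland_altman(x, x + 7)
  expect_equal(ba2$bias, -7)
  expect_identical(ba2$sd_diff, 0)

  expect_error(paired_t(x, x + 7), "degenerate")
  expect_error(bland_altman(1, 2), "n >= 2")
  expect_error(bland_altman(1:3, c(1, NA, 3)), "missing")
  expect_error(bland_altman(1:3, 4:6, ids = c(1, 1, 2)), "unique")
})

test_that("antisymmetric differences give t = 0 and p = 1", {
  a <- c(5, 5, 5, 5); b <- a - c(2, -2, 2, -2)
  pt_ <- paired_t(a, b)
  expect_equal(pt_$t_stat, 0)
  expect_equal(pt_$p_two_sided, 1)
})

test_that("agreement matches brute-force arithmetic on random series", {
  for (s in 1:200) {
    n <- withr::with_seed(s, sample(2:40, 1))
    a <- withr::with_seed(s + 1e4, rnorm(n, 50, 20))
    b <- withr::with_seed(s + 2e4, rnorm(n, 50, 20))
    ba <- bland_altman(a, b)
    o <- oracle_bland_altman(a, b)
    expect_equal(ba$bias, o$bias, tolerance = 1e-9)
    expect_equal(ba$sd_diff, o$sd_diff, tolerance = 1e-9)
    expect_equal(ba$loa_low, o$loa_low, tolerance = 1e-9)
    expect_equal(ba$loa_high, o$loa_high, tolerance = 1e-9)
    if (!is.na(o$t_stat)) {
      expect_equal(ba$t_stat, o$t_stat, tolerance = 1e-9)
      expect_equal(ba$p_two_sided, o$p, tolerance = 1e-9)
    }
  }
})

test_that("agreement obeys scale equivariance and swap antisymmetry", {
  a <- withr::with_seed(5, rnorm(25, 100, 30))
  b <- withr::with_seed(6, rnorm(25, 90, 25))
  ba <- bland_altman(a, b)
  k <- 3.7
  bak <- bland_altman(k * a, k * b)
  expect_equal(bak$bias, k * ba$bias)
  expect_equal(bak$sd_diff, k * ba$sd_diff)
  expect_equal(bak$loa_low, k * ba$loa_low)
  swapped <- bland_altman(b, a)
  expect_equal(swapped$bias, -ba$bias)
  expect_equal(swapped$t_stat, -ba$t_stat)
  expect_equal(swapped$p_two_sided, ba$p_two_sided)
  expect_equal(swapped$loa_high - swapped$loa_low, ba$loa_high - ba$loa_low)
})

test_that("tidy, glance and autoplot expose the report", {
  ba <- bland_altman(c(10, 20, 30), c(12, 19, 33), metric_name = "n_branch_points")
  td <- tidy(ba)
  expect_identical(nrow(td), 3L)
  expect_equal(td$mean, c(11, 19.5, 31.5))
  expect_equal(td$diff, c(-2, 1, -3))
  gl <- glance(ba)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$bias, ba$bias)
  p <- autoplot(ba)
  expect_s3_class(p, "ggplot")
})

test_that("compare_methods aligns, joins and reports per pair and metric", {
  df <- tidyr::expand_grid(image_id = sprintf("img_%02d", 1:10),
                           method = c("alpha", "beta"),
                           metric = "n_branch_points")
  df$value <- withr::with_seed(1, rpois(nrow(df), 50))
  # identical methods agree exactly
  df2 <- df; df2$value[df2$method == "beta"] <-
    df2$value[df2$method == "alpha"]
  cmp <- compare_methods(df2)
  expect_equal(cmp$bias, 0)
  expect_identical(cmp$n, 10L)

  # proportional bias: method beta = 1.1 * alpha shows differences that
  # grow with the pair mean
  df3 <- df; df3$value[df3$method == "beta"] <-
    1.1 * df3$value[df3$method == "alpha"]
  cmp3 <- compare_methods(df3, methods = c("beta", "alpha"))
  rep3 <- attr(cmp3, "reports")[[1]]
  td <- tidy(rep3)
  fit <- stats::lm(diff ~ mean, data = td)
  expect_gt(stats::coef(fit)["mean"], 0)

  # unmatched ids warn and are reported, not silently dropped
  df4 <- df[!(df$image_id == "img_01" & df$method == "beta"), ]
  expect_warning(cmp4 <- compare_methods(df4), "without a counterpart")
  expect_identical(cmp4$n, 9L)
  expect_true("img_01" %in% attr(cmp4, "unmatched_ids")[[1]])

  expect_error(compare_methods(df[, c("image_id", "method")]), "missing column")
  expect_error(compare_methods(df[df$method == "alpha", ]), "at least two")
})

test_that("manual and automated branch counts agree exactly on truth masks", {
  rows <- lapply(c(2, 4), function(s) {
    smp <- default_sample(seed = s)
    sk <- skeletonize_mask(smp$truth_mask)
    tibble::tibble(image_id = paste0("img_", s),
                   method = c("manual", "skeleton"),
                   metric = "n_branch_points",
                   value = c(manual_branch_points(sk), count_branch_points(sk)))
  })
  cmp <- compare_methods(dplyr::bind_rows(rows))
  expect_identical(cmp$bias, 0)
  expect_identical(cmp$sd_diff, 0)
})
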