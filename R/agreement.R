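# Method-agreement statistics: Bland-Altman bias and limits of
# agreement, paired t-tests, and batch method-pair comparison tables.

#' Bland-Altman agreement between two paired measurement series
#'
#' Differences are oriented `a - b` (first-named method minus second);
#' the orientation is recorded in the result. Bias is the mean
#' difference, `sd_diff` the sample standard deviation (n - 1
#' denominator) of the differences, and the limits of agreement are
#' `bias -/+ z * sd_diff` with `z = 1.96`, the interval expected to
#' contain ~95% of between-method differences. The paired t statistic
#' `bias / (sd_diff / sqrt(n))` with `n - 1` degrees of freedom tests
#' for nonzero bias; with `sd_diff = 0` the report is valid but the t
#' statistic is flagged undefined (`NA`).
#'
#' @param a,b numeric vectors of paired measurements (same length,
#'   `n >= 2`, no missing values).
#' @param ids optional unique identifiers per pair.
#' @param method_names length-2 character, names of methods A and B.
#' @param metric_name optional metric label.
#' @param z quantile multiplier for the limits of agreement. The
#'   conventional 1.96 is the default and is kept literal in reports.
#' @return An object of class `camq_agreement`: list with `n`, `bias`,
#'   `sd_diff`, `loa_low`, `loa_high`, `t_stat`, `df`, `p_two_sided`,
#'   `z`, `method_names`, `metric_name` and `data` (tibble with per-pair
#'   `id`, `a`, `b`, `mean`, `diff`).
#' @export
bland_altman <- function(a, b, ids = NULL,
                         method_names = c("A", "B"),
                         metric_name = NULL, z = 1.96) {
  if (length(a) != length(b))
    stop("paired series must have equal length", call. = FALSE)
  n <- length(a)
  if (n < 2) stop("Bland-Altman analysis needs n >= 2 pairs", call. = FALSE)
  if (anyNA(a) || anyNA(b))
    stop("paired series must not contain missing values", call. = FALSE)
  if (is.null(ids)) ids <- seq_len(n)
  if (anyDuplicated(ids)) stop("pair ids must be unique", call. = FALSE)
  d <- a - b
  bias <- mean(d)
  sd_diff <- sd(d)
  if (sd_diff > 0) {
    t_stat <- bias / (sd_diff / sqrt(n))
    p <- 2 * pt(-abs(t_stat), df = n - 1)
  } else {
    t_stat <- NA_real_
    p <- NA_real_
  }
  structure(list(n = n, bias = bias, sd_diff = sd_diff,
                 loa_low = bias - z * sd_diff,
                 loa_high = bias + z * sd_diff,
                 t_stat = t_stat, df = n - 1L, p_two_sided = p, z = z,
                 method_names = method_names, metric_name = metric_name,
                 data = tibble::tibble(id = ids, a = a, b = b,
                                       mean = (a + b) / 2, diff = d)),
            class = "camq_agreement")
}

#' Paired t-test for two measurement series
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` on the differences `d = a - b`,
#' with `df = n - 1` and a two-sided p-value from the t distribution.
#'
#' @param a,b numeric vectors of paired measurements, `n >= 2`.
#' @return A one-row tibble with `t_stat`, `df`, `p_two_sided`.
#' @export
paired_t <- function(a, b) {
  ba <- bland_altman(a, b)
  if (ba$sd_diff == 0)
    stop("paired t-test is degenerate: all differences are identical",
         call. = FALSE)
  tibble::tibble(t_stat = ba$t_stat, df = ba$df, p_two_sided = ba$p_two_sided)
}

#' @export
print.camq_agreement <- function(x, ...) {
  nm <- paste(x$method_names, collapse = " - ")
  cat("<camq_agreement> ", nm,
      if (!is.null(x$metric_name)) paste0(" [", x$metric_name, "]"), "\n",
      "  n = ", x$n, ", bias = ", format(x$bias, digits = 6),
      ", SD(diff) = ", format(x$sd_diff, digits = 6), "\n",
      "  LoA (z = ", x$z, "): [", format(x$loa_low, digits = 6), ", ",
      format(x$loa_high, digits = 6), "]\n",
      "  paired t = ", format(x$t_stat, digits = 6), ", df = ", x$df,
      ", p = ", format(x$p_two_sided, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @describeIn bland_altman per-pair plot data: one row per pair with
#'   `id`, `a`, `b`, `mean`, `diff`.
#' @param x a `camq_agreement` object.
#' @param ... unused.
#' @method tidy camq_agreement
#' @export
tidy.camq_agreement <- function(x, ...) {
  x$data
}

#' @describeIn bland_altman one-row summary with `n`, `bias`,
#'   `sd_diff`, `loa_low`, `loa_high`, `t_stat`, `df`, `p_two_sided`.
#' @method glance camq_agreement
#' @export
glance.camq_agreement <- function(x, ...) {
  tibble::tibble(n = x$n, bias = x$bias, sd_diff = x$sd_diff,
                 loa_low = x$loa_low, loa_high = x$loa_high,
                 t_stat = x$t_stat, df = x$df, p_two_sided = x$p_two_sided)
}

#' @describeIn bland_altman Bland-Altman plot: per-pair differences
#'   against pair means, bias as a solid green line, limits of
#'   agreement as dashed red lines.
#' @param object a `camq_agreement` object.
#' @method autoplot camq_agreement
#' @export
autoplot.camq_agreement <- function(object, ...) {
  nm <- paste(object$method_names, collapse = " - ")
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$bias, color = "darkgreen") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        color = "red", linetype = "dashed") +
    ggplot2::labs(x = paste0("Mean of methods (", nm, ")"),
                  y = paste0("Difference (", nm, ")"),
                  title = object$metric_name %||% "Bland-Altman agreement") +
    ggplot2::theme_minimal()
}

#' Compare all method pairs on a long results table
#'
#' Takes per-image measurements in long format (`image_id, method,
#' metric, value`), aligns every pair of methods on the image ids they
#' share (inner join; unmatched ids are reported via the
#' `"unmatched_ids"` attribute, never silently dropped from counts),
#' and runs [bland_altman()] per method pair and metric.
#'
#' @param df data frame with columns `image_id`, `method`, `metric`,
#'   `value`.
#' @param methods optional character vector restricting (and ordering)
#'   the methods compared; differences are oriented first minus second
#'   within each pair.
#' @param metrics optional character vector restricting the metrics.
#' @param z limits-of-agreement multiplier, default 1.96.
#' @return A tibble with one row per (method pair x metric): `metric`,
#'   `method_a`, `method_b`, `n`, `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `t_stat`, `df`, `p_two_sided`. The full
#'   `camq_agreement` objects (with plot data) are in attribute
#'   `"reports"`, keyed `"<metric>|<method_a>|<method_b>"`.
#' @export
compare_methods <- function(df, methods = NULL, metrics = NULL, z = 1.96) {
  needed <- c("image_id", "method", "metric", "value")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("results table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- tibble::as_tibble(df)
  if (is.null(methods)) methods <- unique(df$method)
  if (is.null(metrics)) metrics <- unique(df$metric)
  df <- dplyr::filter(df, .data$method %in% methods, .data$metric %in% metrics)
  df <- dplyr::filter(df, !is.na(.data$value))
  if (length(methods) < 2)
    stop("need at least two methods to compare", call. = FALSE)
  reports <- list()
  rows <- list()
  unmatched <- list()
  for (m in metrics) {
    dm <- dplyr::filter(df, .data$metric == m)
    have <- intersect(methods, unique(dm$method))
    if (length(have) < 2) next
    for (i in seq_len(length(have) - 1)) {
      for (j in seq(i + 1, length(have))) {
        wa <- dplyr::filter(dm, .data$method == have[i])
        wb <- dplyr::filter(dm, .data$method == have[j])
        joined <- dplyr::inner_join(
          dplyr::select(wa, "image_id", a = "value"),
          dplyr::select(wb, "image_id", b = "value"),
          by = "image_id")
        un <- setdiff(union(wa$image_id, wb$image_id), joined$image_id)
        key <- paste(m, have[i], have[j], sep = "|")
        if (length(un)) unmatched[[key]] <- un
        if (nrow(joined) < 2) next
        ba <- bland_altman(joined$a, joined$b, ids = joined$image_id,
                           method_names = c(have[i], have[j]),
                           metric_name = m, z = z)
        reports[[key]] <- ba
        rows[[key]] <- dplyr::bind_cols(
          tibble::tibble(metric = m, method_a = have[i], method_b = have[j]),
          glance(ba))
      }
    }
  }
  if (length(unmatched))
    warning("image ids without a counterpart were excluded from: ",
            paste(names(unmatched), collapse = "; "), call. = FALSE)
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(metric = character(), method_a = character(),
                   method_b = character(), n = integer(), bias = numeric(),
                   sd_diff = numeric(), loa_low = numeric(),
                   loa_high = numeric(), t_stat = numeric(), df = integer(),
                   p_two_sided = numeric())
  attr(out, "reports") <- reports
  attr(out, "unmatched_ids") <- unmatched
  out
}
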