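# Reproducible emulation of the manual ImageJ protocol: exhaustive
# branch-point marking plus mean thickness of a random sample of
# vessels. Seedable so the "manual" arm of every method comparison can
# be regenerated exactly.

#' Manual-protocol thickness from a random sample of vessels
#'
#' Emulates measuring vessel thickness by hand: `n` skeleton segments
#' ("vessels", as a human sees them) are drawn uniformly without
#' replacement and the thickness at each segment's midpoint pixel is
#' recorded as `2 * r - 1` (`r` = Euclidean distance to background).
#' The result is the mean of the sampled values. Sampling by segment,
#' not by pixel, mirrors the human protocol and avoids weighting long
#' vessels more heavily; the midpoint keeps the measurement away from
#' junctions, where a human would not place a caliper.
#'
#' If fewer than `n` segments exist, every segment is used once and the
#' result is flagged `undersampled`.
#'
#' @param skel a `camq_skeleton` with at least one segment.
#' @param n number of vessels to sample (the protocol's default is 20).
#' @param seed integer seed; fixed seed gives identical samples.
#' @return A one-row tibble (class `camq_manual`) with columns
#'   `n_branch_points`, `sampled_thickness_px`, `n_sampled`, `seed`,
#'   `undersampled`; the sampled midpoint coordinates are in attribute
#'   `"sampled_locations"` (matrix of 1-based `(row, col)`).
#' @export
sample_thickness <- function(skel, n = 20L, seed = 1L) {
  stopifnot(inherits(skel, "camq_skeleton"))
  nseg <- length(skel$segments)
  if (nseg == 0)
    stop("cannot sample vessel thickness from an empty skeleton", call. = FALSE)
  undersampled <- nseg < n
  take <- if (undersampled) seq_len(nseg) else
    withr::with_seed(seed, sample.int(nseg, n))
  locs <- t(vapply(skel$segments[take], function(path) {
    path[ceiling(nrow(path) / 2), ]
  }, numeric(2)))
  thick <- 2 * skel$radius[locs] - 1
  out <- tibble::tibble(n_branch_points = manual_branch_points(skel),
                        sampled_thickness_px = mean(thick),
                        n_sampled = length(take),
                        seed = as.integer(seed),
                        undersampled = undersampled)
  attr(out, "sampled_locations") <- locs
  class(out) <- c("camq_manual", class(out))
  out
}

#' Manual branch-point count
#'
#' The emulated human marks every junction of the vasculature exactly
#' once, which is the same rule as [count_branch_points()] (one count
#' per 8-connected junction cluster). The alias exists so comparison
#' tables carry an explicit "manual" method column.
#'
#' @param skel a `camq_skeleton`.
#' @return Integer count.
#' @export
manual_branch_points <- function(skel) {
  count_branch_points(skel)
}
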