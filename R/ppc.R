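# ImageScope-style positive pixel count: a pure per-pixel HSV color
# classifier with intensity banding and optional exclusion regions
# (the "negative pen tool" workflow around light reflections).

#' Positive-pixel-count configuration
#'
#' Defaults target the dark red of blood-filled vessels; they are this
#' package's choices, not the (unpublished) parameter values of the
#' commercial Positive Pixel Count v9 tool.
#'
#' @param hue_center_deg center of the positive hue band, degrees in
#'   `[0, 360)`; 0 = red.
#' @param hue_width_deg half-width of the hue band (circular), `<= 180`.
#' @param saturation_min minimum HSV saturation (fraction) to count as
#'   positive; rejects near-gray background.
#' @param iwp,imp,isp 8-bit intensity thresholds (`iwp >= imp >= isp`)
#'   splitting positives by HSV value `V` into weak
#'   (`imp < V <= iwp`), medium (`isp < V <= imp`) and strong
#'   (`V <= isp`); strong = darkest = most stain-like. Pixels brighter
#'   than `iwp` are negative regardless of hue.
#' @return A named list of class `camq_ppc_config`.
#' @export
ppc_config <- function(hue_center_deg = 0, hue_width_deg = 30,
                       saturation_min = 0.15,
                       iwp = 220, imp = 175, isp = 130) {
  if (hue_width_deg > 180 || hue_width_deg < 0)
    stop("hue_width_deg must be in [0, 180]", call. = FALSE)
  if (!(iwp >= imp && imp >= isp))
    stop("intensity thresholds must satisfy iwp >= imp >= isp", call. = FALSE)
  structure(list(hue_center_deg = hue_center_deg %% 360,
                 hue_width_deg = hue_width_deg,
                 saturation_min = saturation_min,
                 iwp = iwp, imp = imp, isp = isp),
            class = "camq_ppc_config")
}

#' Classify pixels into positive bands
#'
#' Converts the image to HSV; a pixel is positive iff its hue lies
#' within `hue_center_deg +/- hue_width_deg` (circular distance) and its
#' saturation is `>= saturation_min` and its value (8-bit) is
#' `<= iwp`. Positives are banded into weak / medium / strong by the
#' intensity thresholds (strong = darkest). Excluded pixels are not
#' classified and are removed from the percentage denominator.
#'
#' @param image numeric `h x w x 3` array in `[0, 1]`.
#' @param config a [ppc_config()].
#' @param exclusion optional logical matrix of pixels to exclude (same
#'   dimensions as the image).
#' @return A one-row tibble (class `camq_ppc`) with columns `n_strong`,
#'   `n_medium`, `n_weak`, `n_negative`, `n_excluded`,
#'   `strong_positive_pct` (`100 * n_strong / (total - n_excluded)`).
#'   The five counts always sum to the pixel total.
#' @export
classify_pixels <- function(image, config = ppc_config(), exclusion = NULL) {
  stopifnot(inherits(config, "camq_ppc_config"))
  if (length(dim(image)) != 3 || dim(image)[3] < 3)
    stop("expected an h x w x 3 image array", call. = FALSE)
  h <- dim(image)[1]; w <- dim(image)[2]
  total <- h * w
  if (!is.null(exclusion)) {
    exclusion <- as_mask(exclusion)
    if (!all(dim(exclusion) == c(h, w)))
      stop("exclusion mask dimensions do not match the image", call. = FALSE)
  } else exclusion <- matrix(FALSE, h, w)
  n_excl <- sum(exclusion)
  if (n_excl == total)
    stop_undefined_metric("all pixels excluded: positive percentage undefined")

  hsv <- rgb2hsv(r = as.vector(image[, , 1]), g = as.vector(image[, , 2]),
                 b = as.vector(image[, , 3]), maxColorValue = 1)
  hue <- hsv[1, ] * 360
  sat <- hsv[2, ]
  val8 <- hsv[3, ] * 255
  dh <- abs(((hue - config$hue_center_deg + 180) %% 360) - 180)
  pos <- dh <= config$hue_width_deg & sat >= config$saturation_min &
    val8 <= config$iwp
  excl <- as.vector(exclusion)
  pos <- pos & !excl
  strong <- pos & val8 <= config$isp
  medium <- pos & val8 > config$isp & val8 <= config$imp
  weak <- pos & val8 > config$imp
  n_strong <- sum(strong); n_medium <- sum(medium); n_weak <- sum(weak)
  n_negative <- total - n_excl - n_strong - n_medium - n_weak
  stopifnot(n_strong + n_medium + n_weak + n_negative + n_excl == total)
  out <- tibble::tibble(n_strong = as.integer(n_strong),
                        n_medium = as.integer(n_medium),
                        n_weak = as.integer(n_weak),
                        n_negative = as.integer(n_negative),
                        n_excluded = as.integer(n_excl),
                        strong_positive_pct = 100 * n_strong / (total - n_excl))
  attr(out, "config") <- config
  class(out) <- c("camq_ppc", class(out))
  out
}

#' Effect of excluding artifact pixels on the positive pixel count
#'
#' Runs [classify_pixels()] on a rendered sample twice — once ignoring
#' artifacts, once excluding the sample's `artifact_mask` — and returns
#' both reports with the difference in strong-positive percentage
#' (`with exclusion - without`). On an artifact-free sample the
#' difference is exactly zero.
#'
#' @param sample a `camq_sample`.
#' @param config a [ppc_config()].
#' @return A list of class `camq_ppc_sweep`: `without_exclusion`,
#'   `with_exclusion` (both `camq_ppc`), `strong_positive_pct_diff`.
#' @export
sweep_exclusion_effect <- function(sample, config = ppc_config()) {
  stopifnot(inherits(sample, "camq_sample"))
  without <- classify_pixels(sample$image, config)
  with_ex <- classify_pixels(sample$image, config, exclusion = sample$artifact_mask)
  structure(list(without_exclusion = without,
                 with_exclusion = with_ex,
                 strong_positive_pct_diff =
                   with_ex$strong_positive_pct - without$strong_positive_pct),
            class = "camq_ppc_sweep")
}

#' @export
print.camq_ppc_sweep <- function(x, ...) {
  cat("<camq_ppc_sweep> strong-positive ",
      sprintf("%.3f%%", x$without_exclusion$strong_positive_pct),
      " -> ", sprintf("%.3f%%", x$with_exclusion$strong_positive_pct),
      " after exclusion (diff ",
      sprintf("%+.3f", x$strong_positive_pct_diff), ")\n", sep = "")
  invisible(x)
}
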