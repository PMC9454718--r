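# Classical multiscale tubularity segmentation of dark vessels on a
# bright membrane, plus mask I/O. This is a documented classical
# stand-in behind the same contract a learned segmenter honors:
# RGB image in, binary mask at input resolution out. Externally produced
# masks (e.g. from a CNN tool) enter through load_mask().

#' Segmentation configuration
#'
#' @param tubularity_scales_px Gaussian scales (sigma, px) of the
#'   multiscale ridge filter; must be positive and sorted ascending.
#'   Scales should bracket the expected vessel *radii*.
#' @param channel_weights RGB -> scalar projection weights. The default
#'   `c(0, 1, 0)` uses the green channel, where hemoglobin contrast is
#'   strongest; the projection is inverted internally so dark vessels
#'   become bright ridges.
#' @param threshold `"otsu"` (default) or a numeric threshold in `[0,1]`
#'   applied to the normalized tubularity map.
#' @param min_object_px connected foreground components smaller than
#'   this are removed.
#' @param fill_holes_max_px background holes (not connected to the
#'   image border) up to this size are filled.
#' @param darkness_refine if `TRUE` (default), the thresholded
#'   tubularity map is used as a set of seeds and the mask grows to the
#'   full extent of the dark-pixel components (Otsu on the projected
#'   channel) containing a seed. The ridge filter localizes vessels but
#'   its support is narrower than the vessel body; the darkness gate
#'   recovers the full width while tubularity seeding still rejects
#'   texture and bright artifacts.
#' @return A named list of class `camq_seg_config`.
#' @export
segmentation_config <- function(tubularity_scales_px = c(1.5, 2.5, 4, 6),
                                channel_weights = c(0, 1, 0),
                                threshold = "otsu",
                                min_object_px = 60L,
                                fill_holes_max_px = 120L,
                                darkness_refine = TRUE) {
  if (any(tubularity_scales_px <= 0) || is.unsorted(tubularity_scales_px))
    stop("tubularity scales must be positive and sorted", call. = FALSE)
  if (min_object_px < 0 || fill_holes_max_px < 0)
    stop("min_object_px and fill_holes_max_px must be >= 0", call. = FALSE)
  if (length(channel_weights) != 3)
    stop("channel_weights must have length 3", call. = FALSE)
  structure(list(tubularity_scales_px = tubularity_scales_px,
                 channel_weights = channel_weights,
                 threshold = threshold,
                 min_object_px = as.integer(min_object_px),
                 fill_holes_max_px = as.integer(fill_holes_max_px),
                 darkness_refine = isTRUE(darkness_refine)),
            class = "camq_seg_config")
}

# Frangi-style vesselness for bright ridges of a single-channel image.
# Hessian from central differences of the Gaussian-smoothed image,
# scale-normalized by sigma^2; response kept where the principal
# curvature is negative (ridge, not valley).
tubularity_map <- function(x, scales, beta = 0.5) {
  v <- matrix(0, nrow(x), ncol(x))
  for (s in scales) {
    g <- if (min(dim(x)) >= 9) EBImage::gblur(x, sigma = s) else x
    gxx <- shift_clamp(g, 0, 1) + shift_clamp(g, 0, -1) - 2 * g
    gyy <- shift_clamp(g, 1, 0) + shift_clamp(g, -1, 0) - 2 * g
    gxy <- (shift_clamp(g, 1, 1) + shift_clamp(g, -1, -1) -
              shift_clamp(g, 1, -1) - shift_clamp(g, -1, 1)) / 4
    gxx <- gxx * s^2; gyy <- gyy * s^2; gxy <- gxy * s^2
    tmp <- sqrt(((gxx - gyy) / 2)^2 + gxy^2)
    mid <- (gxx + gyy) / 2
    e1 <- mid + tmp
    e2 <- mid - tmp
    # order by magnitude: l1 small, l2 large
    swap <- abs(e1) > abs(e2)
    l1 <- ifelse(swap, e2, e1)
    l2 <- ifelse(swap, e1, e2)
    S2 <- l1^2 + l2^2
    c2 <- max(S2) / 4
    if (c2 <= 0) next
    rb2 <- (l1 / pmin(l2, -1e-12))^2
    vs <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-S2 / (2 * c2)))
    vs[l2 >= 0] <- 0
    v <- pmax(v, vs)
  }
  v
}

#' Segment vessels in an RGB image
#'
#' Projects the image to a scalar channel, inverts it (CAM vessels are
#' dark red on a bright membrane, so tubularity is computed for dark
#' ridges), applies a multiscale Frangi-style ridge filter, thresholds
#' (Otsu by default), removes small components and fills small holes.
#'
#' @param image numeric array `h x w x 3` with values in `[0, 1]`.
#' @param config a [segmentation_config()].
#' @return A logical mask matrix with attribute `provenance =
#'   "camquant-tubularity"`. A contrast-free image yields an empty mask.
#' @export
segment_vessels <- function(image, config = segmentation_config()) {
  stopifnot(inherits(config, "camq_seg_config"))
  if (length(dim(image)) != 3 || dim(image)[3] < 3)
    stop("expected an h x w x 3 image array", call. = FALSE)
  if (any(dim(image)[1:2] == 0)) stop("empty image", call. = FALSE)
  wts <- config$channel_weights / sum(abs(config$channel_weights))
  proj <- image[, , 1] * wts[1] + image[, , 2] * wts[2] + image[, , 3] * wts[3]
  x <- max(proj) - proj                     # dark vessels -> bright ridges
  v <- tubularity_map(x, config$tubularity_scales_px)
  vmax <- max(v)
  if (vmax <= 0) {
    mask <- matrix(FALSE, nrow(proj), ncol(proj))
    attr(mask, "provenance") <- "camquant-tubularity"
    return(mask)
  }
  v <- v / vmax
  thr <- if (identical(config$threshold, "otsu"))
    EBImage::otsu(v, range = c(0, 1)) else config$threshold
  mask <- v > thr
  if (config$darkness_refine && any(mask)) {
    rng <- range(proj)
    if (diff(rng) > 0) {
      pn <- (proj - rng[1]) / diff(rng)
      dark <- pn < EBImage::otsu(pn, range = c(0, 1))
      lab <- label_components(dark, 8)
      seeded <- setdiff(unique(lab[mask & lab > 0]), 0L)
      if (length(seeded)) mask <- mask | (matrix(lab %in% seeded, nrow(lab)))
    }
  }
  mask <- remove_small_objects(mask, config$min_object_px)
  mask <- fill_small_holes(mask, config$fill_holes_max_px)
  attr(mask, "provenance") <- "camquant-tubularity"
  mask
}

remove_small_objects <- function(mask, min_px) {
  if (min_px <= 1 || !any(mask)) return(mask)
  lab <- label_components(mask, 8)
  sz <- tabulate(lab[lab > 0])
  keep <- which(sz >= min_px)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  out[lab %in% keep & lab > 0] <- TRUE
  out
}

# Fill background holes (4-connected, complement of 8-connected
# foreground) of size <= max_px that do not touch the image border.
fill_small_holes <- function(mask, max_px) {
  if (max_px <= 0 || !any(mask)) return(mask)
  bg <- !mask
  lab <- label_components(bg, 4)
  border_labs <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border_labs <- border_labs[border_labs > 0]
  sz <- tabulate(lab[lab > 0])
  fill <- setdiff(which(sz <= max_px), border_labs)
  if (length(fill)) mask[lab %in% fill] <- TRUE
  mask
}

#' Load a binary mask from file
#'
#' Reads a single-channel PNG or TIFF mask, binarizing nonzero values to
#' foreground. A multi-channel file or a file with more than two
#' distinct gray levels triggers a format warning and is still
#' binarized at `> 0` (first channel).
#'
#' @param path file path (`.png`, `.tif`, `.tiff`).
#' @return Logical mask matrix with attribute `provenance = "external"`.
#' @export
load_mask <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path, call. = FALSE)
  x <- read_raster(path)
  if (length(dim(x)) == 3) {
    if (dim(x)[3] > 1)
      warning("multi-channel mask; using first channel", call. = FALSE)
    x <- x[, , 1]
  }
  vals <- unique(as.vector(x))
  if (length(vals) > 2)
    warning("mask is not binary (", length(vals),
            " distinct values); binarizing at > 0", call. = FALSE)
  mask <- x > 0
  attr(mask, "provenance") <- "external"
  mask
}

#' Write a binary mask to a PNG file
#'
#' Single-channel 8-bit PNG with foreground 255, background 0; the
#' format [load_mask()] round-trips bit-exactly.
#'
#' @param mask logical (or numeric) matrix.
#' @param path output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  mask <- as_mask(mask)
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}
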