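# Rendering of a vessel network into a CAM-like RGB image plus an exact
# binary truth mask.
#
# Foreground rule (the mask contract): a pixel belongs to the truth mask
# iff its center lies within the local vessel radius of the centerline,
# i.e. for some polyline edge (p1,r1)->(p2,r2) the Euclidean distance
# from the pixel center to the edge (clamped projection) is <= the
# radius linearly interpolated at the projection point. Ends are
# therefore capped with half-disks.

# Signed coverage field: max over edges of (local radius - distance).
# mask = field >= 0; the field also drives edge anti-aliasing in the
# rendered image.
coverage_field <- function(network, h, w) {
  phi <- matrix(-Inf, h, w)
  for (sg in network$segments) {
    pl <- sg$polyline
    rad <- sg$radius
    for (i in seq_len(nrow(pl) - 1L)) {
      p1 <- pl[i, ]; p2 <- pl[i + 1L, ]
      r1 <- rad[i]; r2 <- rad[i + 1L]
      rmax <- max(r1, r2)
      r_lo <- max(1L, as.integer(floor(min(p1[1], p2[1]) - rmax - 1)) + 1L)
      r_hi <- min(h, as.integer(ceiling(max(p1[1], p2[1]) + rmax + 1)) + 1L)
      c_lo <- max(1L, as.integer(floor(min(p1[2], p2[2]) - rmax - 1)) + 1L)
      c_hi <- min(w, as.integer(ceiling(max(p1[2], p2[2]) + rmax + 1)) + 1L)
      if (r_lo > r_hi || c_lo > c_hi) next
      rr <- (r_lo:r_hi) - 1L      # 0-based pixel-center coordinates
      cc <- (c_lo:c_hi) - 1L
      dR <- p2 - p1
      len2 <- sum(dR^2)
      PR <- matrix(rr - p1[1], length(rr), length(cc))
      PC <- matrix(cc - p1[2], length(rr), length(cc), byrow = TRUE)
      t <- if (len2 > 0) (PR * dR[1] + PC * dR[2]) / len2 else PR * 0
      t[t < 0] <- 0; t[t > 1] <- 1
      dr_ <- PR - t * dR[1]
      dc_ <- PC - t * dR[2]
      d <- sqrt(dr_^2 + dc_^2)
      loc <- (r1 + t * (r2 - r1)) - d
      blk <- phi[r_lo:r_hi, c_lo:c_hi]
      phi[r_lo:r_hi, c_lo:c_hi] <- pmax(blk, loc)
    }
  }
  phi
}

#' Render a vessel network to a CAM-like RGB image
#'
#' Produces the exact binary truth mask (pixel-center inclusion within
#' the local vessel radius) and an 8-bit-style RGB image: dark-red
#' vessels with anti-aliased edges over a bright, weakly textured
#' membrane-like background. The rendered sample carries the network,
#' its ground truth (including the realized mask area) and the
#' generating parameters.
#'
#' @param network a `camq_network` from [generate_network()].
#' @param params the [generator_params()] used (defaults to the ones
#'   stored in the network).
#' @return An object of class `camq_sample`: list with `image`
#'   (`h x w x 3` array in `[0, 1]`), `truth_mask` (logical matrix),
#'   `artifact_mask` (logical matrix, all `FALSE` until
#'   [add_artifacts()]), `network`, `truth` (tibble, see
#'   [network_truth()]), `params`.
#' @export
render_network <- function(network, params = network$params) {
  stopifnot(inherits(network, "camq_network"))
  h <- params$image_height_px; w <- params$image_width_px
  phi <- coverage_field(network, h, w)
  mask <- phi >= 0
  truth <- network_truth(network)
  truth$mask_area_px2 <- as.integer(sum(mask))

  # background: warm bright membrane tone + smoothed noise texture
  withr::with_seed(params$seed + 7L, {
    noise <- matrix(rnorm(h * w), h, w)
    tex <- if (min(h, w) >= 9) EBImage::gblur(noise, sigma = 3) else noise * 0.2
    tex <- 0.05 * tex / max(abs(tex), 1e-9)
    base <- c(0.94, 0.86, 0.80)
    img <- array(0, c(h, w, 3))
    for (k in 1:3) img[, , k] <- pmin(pmax(base[k] + tex, 0), 1)
    # vessels: dark red, alpha from the coverage field (half-pixel soft
    # edge, kept narrow so the colored fringe beyond the mask contract
    # stays small)
    alpha <- pmin(pmax(2 * phi + 0.5, 0), 1)
    vcol <- c(0.45, 0.10, 0.12)
    shade <- matrix(rnorm(h * w, 0, 0.02), h, w)
    for (k in 1:3) {
      vk <- pmin(pmax(vcol[k] + shade, 0), 1)
      img[, , k] <- img[, , k] * (1 - alpha) + vk * alpha
    }
  })
  structure(list(image = img, truth_mask = mask,
                 artifact_mask = matrix(FALSE, h, w),
                 network = network, truth = truth, params = params),
            class = "camq_sample")
}

#' @export
print.camq_sample <- function(x, ...) {
  cat("<camq_sample> ", nrow(x$truth_mask), "x", ncol(x$truth_mask),
      " px, vessel area ", x$truth$mask_area_px2, " px^2, ",
      x$truth$n_branch_points, " branch points, ",
      sum(x$artifact_mask), " artifact px\n", sep = "")
  invisible(x)
}

#' Parameters for image artifact injection
#'
#' Controls the two artifact classes seen in real CAM photographs:
#' specular light reflections (bright ellipses) and out-of-focus deeper
#' vessels (blurred, low-contrast reddish curves). Artifacts corrupt the
#' image only; the truth mask is by definition unaffected.
#'
#' @param n_highlights number of specular highlight ellipses.
#' @param highlight_axes_px length-2 range of ellipse semi-axes.
#' @param highlight_intensity blend factor toward white in `[0, 1]`;
#'   `0` disables highlights entirely.
#' @param n_deep_vessels number of blurred deep-vessel curves.
#' @param deep_radius_px stroke radius of deep vessels.
#' @param deep_contrast blend factor of the deep-vessel paint in
#'   `[0, 1]`; `0` disables them.
#' @param deep_blur_sigma Gaussian sigma for defocus of deep vessels.
#' @param seed integer seed for artifact placement; defaults to the
#'   sample seed + 1000 inside [add_artifacts()] when `NULL`.
#' @return A named list of class `camq_artifact_params`.
#' @export
artifact_params <- function(n_highlights = 3L,
                            highlight_axes_px = c(6, 16),
                            highlight_intensity = 0.85,
                            n_deep_vessels = 2L,
                            deep_radius_px = 6,
                            deep_contrast = 0.45,
                            deep_blur_sigma = 2.5,
                            seed = NULL) {
  structure(list(n_highlights = as.integer(n_highlights),
                 highlight_axes_px = highlight_axes_px,
                 highlight_intensity = highlight_intensity,
                 n_deep_vessels = as.integer(n_deep_vessels),
                 deep_radius_px = deep_radius_px,
                 deep_contrast = deep_contrast,
                 deep_blur_sigma = deep_blur_sigma,
                 seed = seed),
            class = "camq_artifact_params")
}

#' Inject imaging artifacts into a rendered sample
#'
#' Paints specular highlights (bright ellipses emulating light
#' reflections) and blurred low-contrast deep-vessel curves into the RGB
#' image. The truth mask is untouched; `artifact_mask` records every
#' pixel whose color was altered. With both intensities zero the image
#' is returned bit-identical and the artifact mask stays empty.
#'
#' @param sample a `camq_sample` from [render_network()].
#' @param params an [artifact_params()] object.
#' @return The modified `camq_sample`.
#' @export
add_artifacts <- function(sample, params = artifact_params()) {
  stopifnot(inherits(sample, "camq_sample"),
            inherits(params, "camq_artifact_params"))
  h <- nrow(sample$truth_mask); w <- ncol(sample$truth_mask)
  seed <- params$seed %||% (sample$params$seed + 1000L)
  img <- sample$image
  amask <- sample$artifact_mask
  withr::with_seed(seed, {
    # specular highlights: bright rotated ellipses
    if (params$n_highlights > 0 && params$highlight_intensity > 0) {
      for (i in seq_len(params$n_highlights)) {
        ctr <- c(runif(1, 0.1, 0.9) * (h - 1), runif(1, 0.1, 0.9) * (w - 1))
        ax <- runif(2, params$highlight_axes_px[1], params$highlight_axes_px[2])
        th <- runif(1, 0, pi)
        ell <- ellipse_mask(h, w, ctr, ax, th)
        for (k in 1:3)
          img[, , k][ell] <- img[, , k][ell] * (1 - params$highlight_intensity) +
            params$highlight_intensity
        amask <- amask | ell
      }
    }
    # deep vessels: smooth random curves, reddish, defocused
    if (params$n_deep_vessels > 0 && params$deep_contrast > 0) {
      paint <- matrix(-Inf, h, w)
      for (i in seq_len(params$n_deep_vessels)) {
        pl <- random_curve(h, w, n = 14L)
        paint <- pmax(paint, stroke_mask_field(h, w, pl, params$deep_radius_px))
      }
      paint <- pmin(pmax(paint + 0.5, 0), 1)
      if (params$deep_blur_sigma > 0 && min(h, w) >= 9)
        paint <- EBImage::gblur(paint, sigma = params$deep_blur_sigma)
      paint[paint < 0.02] <- 0      # hard support so artifact_mask is exact
      touched <- paint > 0
      dcol <- c(0.72, 0.42, 0.44)   # desaturated deep red, stays in the PPC-positive hue band
      a <- params$deep_contrast * paint
      for (k in 1:3) img[, , k] <- img[, , k] * (1 - a) + dcol[k] * a
      amask <- amask | touched
    }
  })
  sample$image <- pmin(pmax(img, 0), 1)
  sample$artifact_mask <- amask
  sample
}

ellipse_mask <- function(h, w, center, axes, theta) {
  rr <- matrix((seq_len(h) - 1L) - center[1], h, w)
  cc <- matrix((seq_len(w) - 1L) - center[2], h, w, byrow = TRUE)
  u <- rr * cos(theta) + cc * sin(theta)
  v <- -rr * sin(theta) + cc * cos(theta)
  (u / axes[1])^2 + (v / axes[2])^2 <= 1
}

random_curve <- function(h, w, n = 12L) {
  start <- c(runif(1, 0, h - 1), runif(1, 0, w - 1))
  th <- runif(1, 0, 2 * pi)
  step <- max(h, w) / n
  pts <- matrix(NA_real_, n, 2)
  pts[1, ] <- start
  for (i in 2:n) {
    th <- th + rnorm(1, 0, 0.35)
    pts[i, ] <- pmin(pmax(pts[i - 1, ] + step * c(cos(th), sin(th)), 0),
                     c(h - 1, w - 1))
  }
  pts
}

# Distance-based stroke field for a constant-radius polyline (same
# capsule rule as the renderer, unsigned margin).
stroke_mask_field <- function(h, w, pl, radius) {
  net <- structure(list(nodes = NULL,
                        segments = list(list(polyline = pl,
                                             radius = rep(radius, nrow(pl)))),
                        params = NULL),
                   class = "camq_network")
  coverage_field(net, h, w)
}
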