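# Shared fixtures, all built in code at test time.

# Logical mask with a horizontal bar of given width (odd) and length.
bar_mask <- function(h = 40, w = 130, row_center = 20, width = 9,
                     col_from = 11, col_to = 110) {
  m <- matrix(FALSE, h, w)
  half <- (width - 1) / 2
  m[(row_center - half):(row_center + half), col_from:col_to] <- TRUE
  m
}

# '+' made of two 1-px lines crossing at the center of a square mask.
cross_mask <- function(n = 21) {
  m <- matrix(FALSE, n, n)
  mid <- (n + 1) / 2
  m[mid, ] <- TRUE
  m[, mid] <- TRUE
  m
}

# 'T': horizontal 1-px line plus a vertical stem from its center down.
tee_mask <- function(n = 21) {
  m <- matrix(FALSE, n, n)
  mid <- (n + 1) / 2
  m[mid, ] <- TRUE
  m[mid:n, mid] <- TRUE
  m
}

# Uniform-color RGB image.
flat_image <- function(h, w, rgb) {
  img <- array(0, c(h, w, 3))
  for (k in 1:3) img[, , k] <- rgb[k]
  img
}

# Render a binary mask as a vessel-style image (dark red on bright).
mask_as_image <- function(mask, fg = c(0.45, 0.10, 0.12), bg = 0.92) {
  img <- array(bg, c(dim(mask), 3))
  for (k in 1:3) img[, , k][mask] <- fg[k]
  img
}

# A small rendered sample under the package's default study conditions.
default_sample <- function(seed = 1, ...) {
  p <- generator_params(seed = seed, ...)
  render_network(generate_network(p), p)
}

# Parameters used by the ground-truth recovery suite: trees of 2-4
# bifurcation levels with all vessel radii in roughly [2, 6] px.
recovery_params <- function(seed) {
  withr::with_seed(seed * 101, generator_params(
    seed = seed,
    bifurcation_levels = sample(2:4, 1),
    root_radius_px = runif(1, 4, 6),
    radius_taper = 0.85))
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
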