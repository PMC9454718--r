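# Independent brute-force oracles. Deliberately written as plain loops
# and direct enumeration, sharing no code with the package internals
# they check.

# --- skeleton metrics by direct neighborhood enumeration ---------------
# Takes a logical skeleton matrix; returns branch-point count (junction
# pixels clustered by flood fill), segment count (flood-filled runs of
# non-junction pixels), and total length (explicit pairwise adjacency
# walk: 1 orthogonal, sqrt(2) diagonal, each pair once).
oracle_skeleton_metrics <- function(sk) {
  h <- nrow(sk); w <- ncol(sk)
  deg <- matrix(0L, h, w)
  len <- 0
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (!sk[r, c]) next
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > h || cc < 1 || cc > w || !sk[rr, cc]) next
      deg[r, c] <- deg[r, c] + 1L
      # count each pair once: only when neighbor is lexicographically later
      if (dr > 0 || (dr == 0 && dc > 0))
        len <- len + if (dr != 0 && dc != 0) sqrt(2) else 1
    }
  }
  junction <- sk & deg >= 3
  flood_count <- function(member) {
    seen <- matrix(FALSE, h, w)
    n_comp <- 0L
    for (r in seq_len(h)) for (c in seq_len(w)) {
      if (!member[r, c] || seen[r, c]) next
      n_comp <- n_comp + 1L
      stack <- list(c(r, c)); seen[r, c] <- TRUE
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        for (dr in -1:1) for (dc in -1:1) {
          rr <- p[1] + dr; cc <- p[2] + dc
          if (rr < 1 || rr > h || cc < 1 || cc > w) next
          if (member[rr, cc] && !seen[rr, cc]) {
            seen[rr, cc] <- TRUE
            stack[[length(stack) + 1L]] <- c(rr, cc)
          }
        }
      }
    }
    n_comp
  }
  list(n_branch_points = flood_count(junction),
       n_segments = flood_count(sk & deg < 3),
       total_length = len)
}

# --- rasterization by per-pixel point-to-polyline test -----------------
# O(pixels x edges); the same inclusion rule as the renderer's contract,
# evaluated pixel by pixel.
oracle_rasterize <- function(network, h, w) {
  m <- matrix(FALSE, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    pr <- r - 1; pc <- c - 1
    hit <- FALSE
    for (sg in network$segments) {
      pl <- sg$polyline; rad <- sg$radius
      for (i in seq_len(nrow(pl) - 1)) {
        ar <- pl[i, 1]; ac <- pl[i, 2]
        br <- pl[i + 1, 1]; bc <- pl[i + 1, 2]
        l2 <- (br - ar)^2 + (bc - ac)^2
        t <- if (l2 > 0) ((pr - ar) * (br - ar) + (pc - ac) * (bc - ac)) / l2 else 0
        t <- min(max(t, 0), 1)
        qr <- ar + t * (br - ar); qc <- ac + t * (bc - ac)
        d <- sqrt((pr - qr)^2 + (pc - qc)^2)
        if (d <= rad[i] + t * (rad[i + 1] - rad[i])) { hit <- TRUE; break }
      }
      if (hit) break
    }
    m[r, c] <- hit
  }
  m
}

# --- gliding-box lacunarity by exhaustive window enumeration -----------
oracle_lacunarity <- function(mask, r) {
  h <- nrow(mask); w <- ncol(mask)
  masses <- c()
  for (i in seq_len(h - r + 1)) for (j in seq_len(w - r + 1))
    masses <- c(masses, sum(mask[i:(i + r - 1), j:(j + r - 1)]))
  mu <- mean(masses)
  mean((masses - mu)^2) / mu^2 + 1
}

# --- Bland-Altman / paired t by direct arithmetic ----------------------
oracle_bland_altman <- function(a, b, z = 1.96) {
  d <- a - b
  n <- length(d)
  bias <- sum(d) / n
  sd_d <- sqrt(sum((d - bias)^2) / (n - 1))
  t <- if (sd_d > 0) bias / (sd_d / sqrt(n)) else NA_real_
  list(bias = bias, sd_diff = sd_d,
       loa_low = bias - z * sd_d, loa_high = bias + z * sd_d,
       t_stat = t, df = n - 1,
       p = if (!is.na(t)) 2 * stats::pt(-abs(t), n - 1) else NA_real_)
}

# Random blob masks for oracle-equivalence sweeps: thresholded smoothed
# noise gives connected curvy structures with junctions and loops.
random_blob_mask <- function(h, w, seed, frac = 0.35) {
  withr::with_seed(seed, {
    z <- matrix(rnorm(h * w), h, w)
    if (min(h, w) >= 9) z <- EBImage::gblur(z, sigma = 2.5)
    z > stats::quantile(z, 1 - frac)
  })
}
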