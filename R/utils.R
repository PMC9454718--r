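# Low-level raster helpers shared by the skeleton, segmentation and
# generator code. All operate on plain logical/numeric matrices indexed
# [row, col] with row 1 at the top.

# Shift a matrix by (dr, dc), zero-filling vacated cells.
shift_mat <- function(m, dr, dc, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  src_r <- seq_len(h) - dr
  src_c <- seq_len(w) - dc
  ok_r <- src_r >= 1 & src_r <= h
  ok_c <- src_c >= 1 & src_c <= w
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

# Shift with edge replication (clamped indices): derivatives computed
# from these shifts are ~0 in flat regions up to the border, avoiding
# the spurious edge responses zero-filling would create.
shift_clamp <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  src_r <- pmin(pmax(seq_len(h) - dr, 1), h)
  src_c <- pmin(pmax(seq_len(w) - dc, 1), w)
  m[src_r, src_c]
}

# Offsets of the 8-neighborhood, clockwise from north.
NBR8 <- cbind(dr = c(-1, -1, 0, 1, 1, 1, 0, -1),
              dc = c(0, 1, 1, 1, 0, -1, -1, -1))

# Count of TRUE 8-neighbors for every cell of a logical matrix.
neighbor_count8 <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  acc <- matrix(0, nrow(m), ncol(m))
  for (k in seq_len(8)) acc <- acc + shift_mat(m, NBR8[k, 1], NBR8[k, 2])
  acc
}

# Label connected components of a logical matrix (8- or 4-connectivity).
# Returns an integer matrix: 0 = background, 1..k = component labels.
# igraph does the union-find; edges are extracted vectorized.
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  n_fg <- sum(mask)
  if (n_fg == 0) return(lab)
  id <- matrix(0L, h, w)
  id[mask] <- seq_len(n_fg)
  dirs <- list(c(0, 1), c(1, 0))
  if (connectivity == 8) dirs <- c(dirs, list(c(1, 1), c(1, -1)))
  edges <- integer(0)
  for (d in dirs) {
    nb <- shift_mat(id, -d[1], -d[2])   # value of neighbor at (r+dr, c+dc)
    both <- mask & nb > 0
    if (any(both)) edges <- c(edges, rbind(id[both], nb[both]))
  }
  g <- igraph::make_graph(edges, n = n_fg, directed = FALSE)
  comp <- igraph::components(g)$membership
  lab[mask] <- as.integer(comp)
  lab
}

# Integral image (summed-area table) with a zero top row / left column,
# so box sums are S[r2+1,c2+1] - S[r1,c2+1] - S[r2+1,c1] + S[r1,c1].
integral_image <- function(m) {
  s <- apply(m, 2, cumsum)
  s <- t(apply(s, 1, cumsum))
  rbind(0, cbind(0, s))
}

stop_undefined_metric <- function(msg) {
  stop(structure(class = c("camq_undefined_metric", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_mask <- function(x) {
  if (is.logical(x) && is.matrix(x)) return(x)
  if (is.numeric(x) && is.matrix(x)) return(x > 0)
  stop("expected a logical or numeric matrix mask", call. = FALSE)
}
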