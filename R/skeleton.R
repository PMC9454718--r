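# Medial-axis machinery: topology-preserving thinning, spur pruning and
# extraction of the skeleton graph (junction clusters, endpoints,
# inter-junction pixel paths) that all morphometric metrics consume.

# Dihedral (D4) orientation canonicalization. Parallel thinning has a
# directional sweep bias, so the skeleton of a rotated mask is not in
# general the rotation of the skeleton. Thinning in a canonical
# orientation (the lexicographically smallest of the mask's 8 rigid
# transforms) and mapping back makes every scalar skeleton metric
# exactly invariant under 90-degree rotations and mirrors.
rot_cw <- function(m) t(m[nrow(m):1, , drop = FALSE])
flip_lr <- function(m) m[, ncol(m):1, drop = FALSE]

apply_d4 <- function(m, k) {
  if (k > 4) m <- flip_lr(m)
  for (i in seq_len((k - 1) %% 4)) m <- rot_cw(m)
  m
}

invert_d4 <- function(m, k) {
  for (i in seq_len((4 - (k - 1) %% 4) %% 4)) m <- rot_cw(m)
  if (k > 4) m <- flip_lr(m)
  m
}

canonical_d4 <- function(mask) {
  best_k <- 1L
  best <- mask
  best_key <- c(dim(best), as.integer(best))
  for (k in 2:8) {
    cand <- apply_d4(mask, k)
    key <- c(dim(cand), as.integer(cand))
    n <- min(length(key), length(best_key))
    cmp <- key[seq_len(n)] - best_key[seq_len(n)]
    nz <- which(cmp != 0)
    if (length(nz) && cmp[nz[1]] < 0) {
      best_k <- k; best <- cand; best_key <- key
    }
  }
  list(mask = best, k = best_k)
}

# Zhang-Suen thinning. Vectorized over the whole matrix; iterates the
# two sub-passes until no pixel changes. Produces an 8-connected
# 1-px-wide skeleton that preserves the topology of the input.
thin_mask <- function(mask) {
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  if (sum(m) == 0) return(mask & FALSE)
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      # neighbors clockwise from north: P2..P9
      P <- lapply(seq_len(8), function(k) shift_mat(m, NBR8[k, 1], NBR8[k, 2]))
      B <- Reduce(`+`, P)
      Pn <- c(P, P[1])
      A <- Reduce(`+`, lapply(seq_len(8), function(k)
        (Pn[[k]] == 0) * (Pn[[k + 1]] == 1)))
      if (pass == 1) {
        c1 <- P[[1]] * P[[3]] * P[[5]] == 0   # P2*P4*P6
        c2 <- P[[3]] * P[[5]] * P[[7]] == 0   # P4*P6*P8
      } else {
        c1 <- P[[1]] * P[[3]] * P[[7]] == 0   # P2*P4*P8
        c2 <- P[[1]] * P[[5]] * P[[7]] == 0   # P2*P6*P8
      }
      del <- m == 1 & B >= 2 & B <= 6 & A == 1 & c1 & c2
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  remove_redundant_px(m == 1L)
}

# Zhang-Suen leaves staircase doublets (a corner pixel whose neighbors
# are already mutually connected); such pixels read as false junctions.
# Sequentially delete every pixel with >= 2 skeleton neighbors whose
# neighbors form a single 8-connected set without it; repeat until
# stable. Endpoints and true junctions (neighbors in >= 2 components)
# are untouchable, so topology is preserved.
remove_redundant_px <- function(skel) {
  h <- nrow(skel); w <- ncol(skel)
  repeat {
    changed <- FALSE
    idx <- which(skel, arr.ind = TRUE)
    for (i in seq_len(nrow(idx))) {
      r <- idx[i, 1]; c <- idx[i, 2]
      if (!skel[r, c]) next
      nbr <- NULL
      for (k in seq_len(8)) {
        rr <- r + NBR8[k, 1]; cc <- c + NBR8[k, 2]
        if (rr >= 1 && rr <= h && cc >= 1 && cc <= w && skel[rr, cc])
          nbr <- rbind(nbr, c(rr, cc))
      }
      if (is.null(nbr) || nrow(nbr) < 2) next
      if (n_nbr_components(nbr) == 1) {
        skel[r, c] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  skel
}

# Number of 8-connected components among a pixel's foreground neighbors
# (two neighbors are adjacent iff their Chebyshev distance is <= 1).
n_nbr_components <- function(nbr) {
  n <- nrow(nbr)
  comp <- seq_len(n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (max(abs(nbr[i, ] - nbr[j, ])) <= 1) {
        old <- comp[j]; new <- comp[i]
        comp[comp == old] <- new
      }
    }
  }
  length(unique(comp))
}

# Iteratively remove terminal branches shorter than `prune_px`
# (geodesic length: 1 per orthogonal step, sqrt(2) per diagonal step).
# Only spurs that end at a junction are removed, so short isolated
# structures (e.g. the skeleton of a blob) survive.
prune_spurs <- function(skel, prune_px) {
  if (prune_px <= 0 || sum(skel) == 0) return(skel)
  repeat {
    nc <- neighbor_count8(skel)
    ends <- which(skel & nc == 1, arr.ind = TRUE)
    if (nrow(ends) == 0) break
    removed_any <- FALSE
    for (e in seq_len(nrow(ends))) {
      path <- trace_from_endpoint(skel, nc, ends[e, 1], ends[e, 2], prune_px)
      if (!is.null(path)) {
        skel[path] <- FALSE
        removed_any <- TRUE
        nc <- neighbor_count8(skel)   # degrees change as spurs go
      }
    }
    if (!removed_any) break
  }
  skel
}

# Walk from an endpoint along degree-<=2 pixels; if a junction (>=3
# neighbors) is met before accumulating `limit` length, return the
# linear indices of the spur pixels (junction excluded), else NULL.
trace_from_endpoint <- function(skel, nc, r, c, limit) {
  h <- nrow(skel)
  if (!skel[r, c] || nc[r, c] != 1) return(NULL)
  path <- integer(0)
  len <- 0
  pr <- 0L; pc <- 0L   # previous pixel (0 = none)
  repeat {
    path <- c(path, (c - 1L) * h + r)
    nbr <- NULL
    for (k in seq_len(8)) {
      rr <- r + NBR8[k, 1]; cc <- c + NBR8[k, 2]
      if (rr < 1 || rr > h || cc < 1 || cc > ncol(skel)) next
      if (!skel[rr, cc]) next
      if (rr == pr && cc == pc) next
      nbr <- rbind(nbr, c(rr, cc))
    }
    if (is.null(nbr) || nrow(nbr) == 0) return(NULL)  # isolated line: keep
    if (nrow(nbr) > 1) {
      # multiple continuations: spur has reached a junction cluster
      any_j <- any(apply(nbr, 1, function(p) nc[p[1], p[2]] >= 3))
      return(if (any_j) path else NULL)
    }
    rr <- nbr[1, 1]; cc <- nbr[1, 2]
    len <- len + if (rr != r && cc != c) sqrt(2) else 1
    if (len >= limit) return(NULL)                    # long enough: not a spur
    if (nc[rr, cc] >= 3) return(path)                 # reached a junction: spur
    pr <- r; pc <- c; r <- rr; c <- cc
  }
}

#' Skeletonize a binary mask into a skeleton graph
#'
#' Thins the mask to a 1-pixel-wide, topology-preserving skeleton
#' (Zhang-Suen, applied in a canonical orientation so that all scalar
#' metrics are exactly invariant under 90-degree rotations and
#' mirrors), iteratively removes terminal spurs shorter than
#' `prune_spurs_px` (a thinning artifact at junctions of wide vessels),
#' attaches the exact Euclidean distance to background of the *unpruned*
#' mask to every skeleton pixel, and extracts the graph structure:
#' junction pixels (>= 3 skeleton neighbors, 8-connectivity), junction
#' clusters (8-connected groups of junction pixels, each counted as one
#' branching point), endpoints, and the pixel paths connecting them.
#'
#' @param mask logical matrix (or numeric, binarized at > 0).
#' @param prune_spurs_px prune terminal branches shorter than this
#'   geodesic length (px). Default 5.
#' @return An object of class `camq_skeleton`: list with
#'   * `skeleton` — logical matrix of skeleton pixels;
#'   * `radius` — numeric matrix, Euclidean distance transform of the
#'     input mask sampled on the skeleton (`NA` elsewhere);
#'   * `junctions` — list of junction clusters, each a matrix of
#'     `(row, col)` pixel coordinates (1-based matrix indices);
#'   * `endpoints` — matrix of endpoint coordinates;
#'   * `segments` — list of pixel paths (n x 2 index matrices) between
#'     terminals, each with attributes `length_px` and `ends`;
#'   * `n_junction_pixels`, `n_components`, `prune_spurs_px`, `dim`.
#' @export
skeletonize_mask <- function(mask, prune_spurs_px = 5) {
  mask <- as_mask(mask)
  canon <- canonical_d4(mask)
  skel <- thin_mask(canon$mask)
  skel <- prune_spurs(skel, prune_spurs_px)
  skel <- invert_d4(skel, canon$k)
  h <- nrow(mask); w <- ncol(mask)
  radius <- matrix(NA_real_, h, w)
  if (any(skel)) {
    edt <- edt_mask(mask)
    radius[skel] <- edt[skel]
  }
  g <- extract_graph(skel)
  structure(list(skeleton = skel, radius = radius,
                 junctions = g$junctions, endpoints = g$endpoints,
                 segments = g$segments,
                 n_junction_pixels = g$n_junction_pixels,
                 n_components = g$n_components,
                 prune_spurs_px = prune_spurs_px,
                 dim = c(h, w)),
            class = "camq_skeleton")
}

# Exact Euclidean distance (pixel centers) to the nearest background
# pixel; pixels touching the image border are handled by EBImage's
# padded distance map convention (distance to the border counts).
edt_mask <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  as.matrix(EBImage::distmap(m, metric = "euclidean"))
}

extract_graph <- function(skel) {
  h <- nrow(skel); w <- ncol(skel)
  empty <- list(junctions = list(), endpoints = matrix(numeric(0), 0, 2),
                segments = list(), n_junction_pixels = 0L, n_components = 0L)
  if (!any(skel)) return(empty)
  nc <- neighbor_count8(skel)
  jpx <- skel & nc >= 3
  endpoints <- which(skel & nc <= 1, arr.ind = TRUE)
  jlab <- label_components(jpx, 8)
  njc <- max(jlab)
  junctions <- if (njc > 0)
    lapply(seq_len(njc), function(k) which(jlab == k, arr.ind = TRUE))
  else list()
  # arcs: skeleton minus junction pixels, each 8-connected arc is one segment
  arc <- skel & !jpx
  alab <- label_components(arc, 8)
  nseg <- max(alab)
  segments <- vector("list", nseg)
  if (nseg > 0) {
    idx <- which(alab > 0, arr.ind = TRUE)
    labs <- alab[alab > 0]
    ord <- order(labs)
    idx <- idx[ord, , drop = FALSE]
    labs <- labs[ord]
    starts <- c(1L, which(diff(labs) != 0) + 1L, length(labs) + 1L)
    for (k in seq_len(nseg)) {
      px <- idx[starts[k]:(starts[k + 1L] - 1L), , drop = FALSE]
      segments[[k]] <- order_arc(px, jlab)
    }
  }
  list(junctions = junctions, endpoints = endpoints, segments = segments,
       n_junction_pixels = as.integer(sum(jpx)),
       n_components = max(label_components(skel, 8)))
}

# Order the pixels of one arc into a path and record which junction
# clusters (by id) or endpoints terminate it. `attr(path, "length_px")`
# is the 1 / sqrt(2) step sum along the ordered path.
order_arc <- function(px, jlab) {
  n <- nrow(px)
  if (n == 1) {
    path <- px
  } else {
    # adjacency among arc pixels
    key <- paste(px[, 1], px[, 2])
    lookup <- setNames(seq_len(n), key)
    adj <- vector("list", n)
    deg <- integer(n)
    for (i in seq_len(n)) {
      for (k in seq_len(8)) {
        nb <- paste(px[i, 1] + NBR8[k, 1], px[i, 2] + NBR8[k, 2])
        j <- lookup[nb]
        if (!is.na(j)) { adj[[i]] <- c(adj[[i]], j); deg[i] <- deg[i] + 1L }
      }
    }
    start <- which(deg <= 1)[1]
    if (is.na(start)) start <- 1L   # closed loop
    ordv <- integer(n)
    visited <- logical(n)
    cur <- start
    for (i in seq_len(n)) {
      ordv[i] <- cur
      visited[cur] <- TRUE
      nxt <- adj[[cur]][!visited[adj[[cur]]]]
      if (length(nxt) == 0) { ordv <- ordv[seq_len(i)]; break }
      cur <- nxt[1]
    }
    path <- px[ordv, , drop = FALSE]
  }
  d <- abs(diff(path))
  attr(path, "length_px") <- if (nrow(path) > 1)
    sum(ifelse(rowSums(d) == 2, sqrt(2), 1)) else 0
  # terminal attachments: junction cluster ids adjacent to the arc ends
  ends_att <- lapply(list(path[1, ], path[nrow(path), ]), function(p) {
    labs <- integer(0)
    for (k in seq_len(8)) {
      r <- p[1] + NBR8[k, 1]; c <- p[2] + NBR8[k, 2]
      if (r >= 1 && r <= nrow(jlab) && c >= 1 && c <= ncol(jlab) && jlab[r, c] > 0)
        labs <- c(labs, jlab[r, c])
    }
    unique(labs)
  })
  attr(path, "ends") <- ends_att
  path
}

#' @export
print.camq_skeleton <- function(x, ...) {
  cat("<camq_skeleton> ", sum(x$skeleton), " px, ",
      length(x$junctions), " branch points, ",
      length(x$segments), " segments, ",
      nrow(x$endpoints), " endpoints (prune ", x$prune_spurs_px, " px)\n",
      sep = "")
  invisible(x)
}
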