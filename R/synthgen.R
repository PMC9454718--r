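#' Parameters for the synthetic vascular network generator
#'
#' Bundles the geometric and rendering parameters of the seeded generator.
#' All extents are in pixels; angles in degrees. Defaults describe a
#' single vascular tree occupying a 320 x 320 px field of view, with
#' radii tapering toward the tips the way CAM capillaries thin out
#' distally.
#'
#' @param image_height_px,image_width_px image extent in pixels.
#' @param n_roots number of independent trees seeded at the image border.
#' @param bifurcation_levels number of bifurcation generations; `0` gives
#'   a single unbranched segment per root.
#' @param branch_angle_deg length-2 numeric `c(mean, jitter)`: half-angle
#'   between daughter branches, jittered uniformly by `+/- jitter`.
#' @param segment_length_px length-2 numeric `c(mean, jitter)` for the
#'   root-level segment length; deeper levels shrink by
#'   `segment_length_taper` per generation.
#' @param segment_length_taper multiplicative per-level shrink of segment
#'   length, in `(0, 1]`.
#' @param root_radius_px vessel radius at the root, in pixels.
#' @param radius_taper multiplicative per-level shrink of the radius, in
#'   `(0, 1]`; rendered radii are clamped at 1 px.
#' @param curvature_jitter standard deviation (radians) of the random
#'   heading increment applied at each ~4 px step along a segment; `0`
#'   gives straight segments.
#' @param seed integer seed; the generator is fully deterministic given
#'   the parameter set.
#'
#' @return An object of class `camq_params` (a named list).
#' @export
generator_params <- function(image_height_px = 320L,
                             image_width_px = 320L,
                             n_roots = 1L,
                             bifurcation_levels = 3L,
                             branch_angle_deg = c(mean = 32, jitter = 8),
                             segment_length_px = c(mean = 60, jitter = 9),
                             segment_length_taper = 0.85,
                             root_radius_px = 4,
                             radius_taper = 0.8,
                             curvature_jitter = 0.03,
                             seed = 1L) {
  p <- list(image_height_px = as.integer(image_height_px),
            image_width_px = as.integer(image_width_px),
            n_roots = as.integer(n_roots),
            bifurcation_levels = as.integer(bifurcation_levels),
            branch_angle_deg = unname(branch_angle_deg),
            segment_length_px = unname(segment_length_px),
            segment_length_taper = segment_length_taper,
            root_radius_px = root_radius_px,
            radius_taper = radius_taper,
            curvature_jitter = curvature_jitter,
            seed = as.integer(seed))
  validate_generator_params(p)
  structure(p, class = "camq_params")
}

validate_generator_params <- function(p) {
  if (p$image_height_px < 1 || p$image_width_px < 1)
    stop("image extent must be positive", call. = FALSE)
  if (p$n_roots < 1) stop("n_roots must be >= 1", call. = FALSE)
  if (p$bifurcation_levels < 0) stop("bifurcation_levels must be >= 0", call. = FALSE)
  if (length(p$branch_angle_deg) != 2 || length(p$segment_length_px) != 2)
    stop("branch_angle_deg and segment_length_px must be c(mean, jitter)", call. = FALSE)
  if (p$segment_length_px[1] <= 0) stop("segment length must be positive", call. = FALSE)
  if (p$radius_taper <= 0 || p$radius_taper > 1)
    stop("radius_taper must be in (0, 1]", call. = FALSE)
  if (p$segment_length_taper <= 0 || p$segment_length_taper > 1)
    stop("segment_length_taper must be in (0, 1]", call. = FALSE)
  if (p$root_radius_px <= 0) stop("root_radius_px must be positive", call. = FALSE)
  invisible(p)
}

# Radius at a given bifurcation level, clamped so rendered radii stay
# >= 1 px (thin distal capillaries still cover one pixel row).
level_radius <- function(p, level) max(1, p$root_radius_px * p$radius_taper^level)

#' Generate a synthetic vascular network
#'
#' Grows `n_roots` recursive bifurcating trees from the image border.
#' Each segment is a polyline with a small random-walk curvature and a
#' linearly tapering radius; at each bifurcation the two daughters leave
#' at `+/- branch_angle` around the parent heading. Segments are clipped
#' at the image border and any subtree distal to the clip is dropped, so
#' the returned network (and hence the ground truth computed from it)
#' reflects exactly what can be rendered.
#'
#' @param params a [generator_params()] object.
#' @return An object of class `camq_network`: a list with
#'   * `nodes` — tibble `(id, row, col, kind)`, `kind` one of
#'     `"root"`, `"branch"`, `"tip"`;
#'   * `segments` — list of segments, each with `polyline` (n x 2 matrix
#'     of `(row, col)`), `radius` (per-point radius, px), `from`, `to`
#'     (node ids), `level`;
#'   * `params` — the generating parameters.
#' @export
generate_network <- function(params) {
  validate_generator_params(params)
  withr::with_seed(params$seed, generate_network_impl(params))
}

generate_network_impl <- function(p) {
  h <- p$image_height_px; w <- p$image_width_px
  env <- new.env()
  env$nodes <- list()     # list of c(row, col), kind
  env$kinds <- character()
  env$segments <- list()

  add_node <- function(rc, kind) {
    env$nodes[[length(env$nodes) + 1L]] <- rc
    env$kinds[length(env$kinds) + 1L] <- kind
    length(env$nodes)
  }
  in_bounds <- function(rc) rc[1] >= 0 && rc[1] <= h - 1 && rc[2] >= 0 && rc[2] <= w - 1

  # Grow one segment from `pos` along `heading` (radians); returns the
  # clipped polyline and whether it reached its full length.
  grow_polyline <- function(pos, heading, len) {
    step <- 4
    n_steps <- max(2L, ceiling(len / step))
    ds <- len / n_steps
    pts <- matrix(NA_real_, n_steps + 1L, 2L)
    pts[1L, ] <- pos
    th <- heading
    complete <- TRUE
    n_kept <- 1L
    for (i in seq_len(n_steps)) {
      th <- th + rnorm(1L, 0, p$curvature_jitter)
      nxt <- pts[n_kept, ] + ds * c(-cos(th), sin(th))  # row decreases upward
      if (!in_bounds(nxt)) {
        # truncate at the border along the current step direction
        cur <- pts[n_kept, ]
        t_max <- 1
        for (k in 1:2) {
          d <- nxt[k] - cur[k]
          lim <- if (k == 1) h - 1 else w - 1
          if (d > 0) t_max <- min(t_max, (lim - cur[k]) / d)
          if (d < 0) t_max <- min(t_max, (0 - cur[k]) / d)
        }
        t_max <- max(t_max, 0)
        if (t_max > 1e-6) {
          n_kept <- n_kept + 1L
          pts[n_kept, ] <- cur + t_max * (nxt - cur)
        }
        complete <- FALSE
        break
      }
      n_kept <- n_kept + 1L
      pts[n_kept, ] <- nxt
    }
    list(polyline = pts[seq_len(n_kept), , drop = FALSE],
         heading = th, complete = complete)
  }

  # Clearance of a point against already-grown segments, excluding those
  # incident to `node_id` (the parent stem and the co-sibling share that
  # node and legitimately overlap right at the junction). Emulates the
  # planarity of the real membrane: in-plane vessels do not cross.
  min_clearance <- function(pt, r_self, node_id) {
    best <- Inf
    for (sg in env$segments) {
      if (sg$from == node_id || sg$to == node_id) next
      pl <- sg$polyline
      d1 <- pl[-nrow(pl), , drop = FALSE]
      dR <- pl[-1L, , drop = FALSE] - d1
      len2 <- rowSums(dR^2)
      t <- ((pt[1] - d1[, 1]) * dR[, 1] + (pt[2] - d1[, 2]) * dR[, 2]) /
        pmax(len2, 1e-12)
      t <- pmin(pmax(t, 0), 1)
      dd <- sqrt((pt[1] - d1[, 1] - t * dR[, 1])^2 +
                   (pt[2] - d1[, 2] - t * dR[, 2])^2)
      r1 <- sg$radius[-length(sg$radius)]
      r2 <- sg$radius[-1L]
      rloc <- r1 + t * (r2 - r1)
      best <- min(best, min(dd - rloc - r_self))
    }
    best
  }

  grow_tree <- function(pos, heading, level, parent_id) {
    len_mean <- p$segment_length_px[1] * p$segment_length_taper^level
    len_jit <- p$segment_length_px[2] * p$segment_length_taper^level
    len <- max(2, len_mean + runif(1L, -len_jit, len_jit))
    gp <- grow_polyline(pos, heading, len)
    pl <- gp$polyline
    if (nrow(pl) < 2L) return(invisible(NULL))
    r0 <- level_radius(p, level)
    r1 <- level_radius(p, level + 1L)
    # truncate at the first point that would collide with a non-adjacent
    # vessel; the collision clearance is one pixel of free membrane
    if (length(env$segments) > 0) {
      cut <- 0L
      for (i in 2:nrow(pl)) {
        if (min_clearance(pl[i, ], max(r0, r1), parent_id) < 1) { cut <- i; break }
      }
      if (cut > 0L) {
        if (cut <= 2L) return(invisible(NULL))
        pl <- pl[seq_len(cut - 1L), , drop = FALSE]
        gp$complete <- FALSE
      }
    }
    # a branch shorter than its own diameter is not a vessel: it would
    # be entirely swallowed by the junction cap of its parent
    arc_len <- sum(sqrt(rowSums(diff(pl)^2)))
    if (level > 0 && arc_len < 2 * max(r0, r1) + 2) return(invisible(NULL))
    # radius tapers linearly with arc length along the segment
    s <- c(0, cumsum(sqrt(rowSums(diff(pl)^2))))
    rad <- r0 + (r1 - r0) * s / max(s[length(s)], 1e-9)
    end <- pl[nrow(pl), ]
    can_branch <- gp$complete && level < p$bifurcation_levels
    kind <- if (can_branch) "branch" else "tip"
    end_id <- add_node(end, kind)
    env$segments[[length(env$segments) + 1L]] <-
      list(polyline = pl, radius = rad, from = parent_id, to = end_id,
           level = level)
    if (can_branch) {
      ang <- (p$branch_angle_deg[1] +
                runif(2L, -p$branch_angle_deg[2], p$branch_angle_deg[2])) * pi / 180
      grow_tree(end, gp$heading - ang[1], level + 1L, end_id)
      grow_tree(end, gp$heading + ang[2], level + 1L, end_id)
    }
    invisible(NULL)
  }

  for (root in seq_len(p$n_roots)) {
    side <- sample.int(4L, 1L)                 # 1 bottom, 2 left, 3 top, 4 right
    frac <- runif(1L, 0.25, 0.75)
    pos <- switch(side,
                  c(h - 1, frac * (w - 1)),
                  c(frac * (h - 1), 0),
                  c(0, frac * (w - 1)),
                  c(frac * (h - 1), w - 1))
    heading <- switch(side, 0, pi / 2, pi, -pi / 2)  # inward; 0 = up (row decreasing)
    heading <- heading + runif(1L, -0.3, 0.3)
    root_id <- add_node(pos, "root")
    grow_tree(pos, heading, 0L, root_id)
  }

  net <- finalize_network(env, p)
  net
}

# Recompute node kinds from realized degrees (clipping can drop daughters,
# leaving a former branch node with a single child: such pass-through
# nodes are merged away so every interior node has degree >= 3).
finalize_network <- function(env, p) {
  nodes <- do.call(rbind, env$nodes)
  kinds <- env$kinds
  segs <- env$segments
  n <- length(kinds)
  deg <- integer(n)
  for (sg in segs) {
    deg[sg$from] <- deg[sg$from] + 1L
    deg[sg$to] <- deg[sg$to] + 1L
  }
  # merge degree-2 pass-through nodes (never roots)
  repeat {
    mid <- which(deg == 2L & kinds != "root")
    if (length(mid) == 0L) break
    v <- mid[1L]
    inc <- which(vapply(segs, function(sg) sg$from == v || sg$to == v, logical(1)))
    if (length(inc) != 2L) break   # safety; should not happen for trees
    a <- segs[[inc[1]]]; b <- segs[[inc[2]]]
    # orient a ... -> v, v -> ... b
    if (a$to != v) a <- reverse_segment(a)
    if (b$from != v) b <- reverse_segment(b)
    merged <- list(polyline = rbind(a$polyline, b$polyline[-1L, , drop = FALSE]),
                   radius = c(a$radius, b$radius[-1L]),
                   from = a$from, to = b$to, level = min(a$level, b$level))
    segs[[inc[1]]] <- merged
    segs[[inc[2]]] <- NULL
    deg[v] <- 0L
    kinds[v] <- "dropped"
  }
  keep <- kinds != "dropped" & deg > 0L
  if (!any(keep)) {
    nodes_tbl <- tibble::tibble(id = integer(), row = numeric(),
                                col = numeric(), kind = character())
    return(structure(list(nodes = nodes_tbl, segments = list(), params = p),
                     class = "camq_network"))
  }
  new_id <- cumsum(keep); new_id[!keep] <- NA_integer_
  kinds[deg >= 3L & kinds != "root"] <- "branch"
  kinds[deg == 1L & kinds != "root"] <- "tip"
  segs <- lapply(segs, function(sg) {
    sg$from <- new_id[sg$from]; sg$to <- new_id[sg$to]; sg
  })
  nodes_tbl <- tibble::tibble(id = seq_len(sum(keep)),
                              row = nodes[keep, 1],
                              col = nodes[keep, 2],
                              kind = kinds[keep])
  structure(list(nodes = nodes_tbl, segments = segs, params = p),
            class = "camq_network")
}

reverse_segment <- function(sg) {
  list(polyline = sg$polyline[rev(seq_len(nrow(sg$polyline))), , drop = FALSE],
       radius = rev(sg$radius), from = sg$to, to = sg$from, level = sg$level)
}

#' @export
print.camq_network <- function(x, ...) {
  cat("<camq_network> ", nrow(x$nodes), " nodes, ", length(x$segments),
      " segments, ", sum(x$nodes$kind == "branch"), " branch points\n", sep = "")
  invisible(x)
}

#' Ground truth summary of a vessel network
#'
#' Computes the exact morphometric ground truth of a generated network:
#' branch-point count (nodes of degree >= 3), total centerline length
#' (sum of polyline chord lengths), and the length-weighted mean radius.
#' `mask_area_px2` is only known after rendering and is `NA` here;
#' [render_network()] fills it in.
#'
#' @param network a `camq_network`.
#' @return A one-row tibble with columns `n_branch_points`,
#'   `total_length_px`, `mean_radius_px`, `mask_area_px2`.
#' @export
network_truth <- function(network) {
  stopifnot(inherits(network, "camq_network"))
  kinds <- network$nodes[["kind"]] %||% character()
  n_bp <- sum(kinds == "branch")
  tot_len <- 0
  wsum <- 0
  for (sg in network$segments) {
    d <- sqrt(rowSums(diff(sg$polyline)^2))
    tot_len <- tot_len + sum(d)
    rmid <- (head(sg$radius, -1) + tail(sg$radius, -1)) / 2
    wsum <- wsum + sum(d * rmid)
  }
  tibble::tibble(n_branch_points = n_bp,
                 total_length_px = tot_len,
                 mean_radius_px = if (tot_len > 0) wsum / tot_len else NA_real_,
                 mask_area_px2 = NA_integer_)
}
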