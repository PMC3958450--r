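# Centerline extraction from binary masks.
#
# Two routes to a single-pixel-wide centerline:
#
# * "geodesic" (default): the path between the component's two geodesically
#   most distant pixels, computed with edge costs biased toward the ridge of
#   the Euclidean distance transform, i.e. a discrete medial-axis path. The
#   path spans the object tip to tip, so together with the tube radius it
#   gives an essentially unbiased length estimate even for short fragments.
# * "thinning": classic Zhang-Suen thinning plus spur pruning and
#   longest-geodesic-path decomposition. Iterative thinning retracts the
#   rounded ends of a tubule by roughly its width, which is why it is not
#   the default for measurement; it is kept for mask-level QC and for
#   skeleton topology.

# out[y, x] = m[y + dy, x + dx], zero outside
shift_mat <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(0L, ny, nx)
  yd <- max(1L, 1L - dy):min(ny, ny - dy)
  xd <- max(1L, 1L - dx):min(nx, nx - dx)
  if (length(yd) && length(xd)) out[yd, xd] <- m[yd + dy, xd + dx]
  out
}

# Zhang-Suen thinning of a logical mask; returns a logical skeleton
skeletonize <- function(mask) {
  stopifnot(is.matrix(mask))
  img <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      P2 <- shift_mat(img, -1L, 0L); P3 <- shift_mat(img, -1L, 1L)
      P4 <- shift_mat(img, 0L, 1L);  P5 <- shift_mat(img, 1L, 1L)
      P6 <- shift_mat(img, 1L, 0L);  P7 <- shift_mat(img, 1L, -1L)
      P8 <- shift_mat(img, 0L, -1L); P9 <- shift_mat(img, -1L, -1L)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (P2 == 0L & P3 == 1L) + (P3 == 0L & P4 == 1L) +
           (P4 == 0L & P5 == 1L) + (P5 == 0L & P6 == 1L) +
           (P6 == 0L & P7 == 1L) + (P7 == 0L & P8 == 1L) +
           (P8 == 0L & P9 == 1L) + (P9 == 0L & P2 == 1L)
      cond <- if (step == 1L) {
        P2 * P4 * P6 == 0L & P4 * P6 * P8 == 0L
      } else {
        P2 * P4 * P8 == 0L & P2 * P6 * P8 == 0L
      }
      del <- img == 1L & B >= 2L & B <= 6L & A == 1L & cond
      if (any(del)) { img[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  img == 1L
}

# adjacency of a pixel set (n x 2 (y, x) matrix), 8-connectivity.
# Returns edge list (from, to), Euclidean step lengths, per-pixel values.
pixel_edges <- function(px) {
  key <- px[, 1] * 1e6 + px[, 2]
  from <- integer(0); to <- integer(0); step <- numeric(0)
  for (d in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
    nb <- match((px[, 1] + d[1]) * 1e6 + (px[, 2] + d[2]), key)
    ok <- which(!is.na(nb))
    from <- c(from, ok); to <- c(to, nb[ok])
    step <- c(step, rep(if (all(d != 0)) sqrt(2) else 1, length(ok)))
  }
  list(from = from, to = to, step = step)
}

skeleton_graph <- function(px) {
  n <- nrow(px)
  if (n == 1L) return(igraph::make_empty_graph(1, directed = FALSE))
  e <- pixel_edges(px)
  g <- igraph::make_graph(rbind(e$from, e$to), n = n, directed = FALSE)
  igraph::E(g)$weight <- e$step
  g
}

# medial-axis geodesic: the weighted-shortest path between the two most
# distant pixels, with costs inflated away from the distance-transform ridge
# so the path runs along the tube axis. beta controls the centering bias.
geodesic_centerline <- function(px, edt, beta = 2) {
  n <- nrow(px)
  if (n <= 2L) return(list(path = px, r_mean = 1))
  e <- pixel_edges(px)
  ev <- edt[px]
  rmax <- max(ev)
  w <- e$step * (1 + beta * (1 - (ev[e$from] + ev[e$to]) / (2 * rmax)))
  g <- igraph::make_graph(rbind(e$from, e$to), n = n, directed = FALSE)
  s0 <- which.max(ev)  # start the double sweep from the most interior pixel
  t1 <- which.max(igraph::distances(g, v = s0, weights = w)[1, ])
  t2 <- which.max(igraph::distances(g, v = t1, weights = w)[1, ])
  sp <- igraph::shortest_paths(g, from = t1, to = t2, weights = w)$vpath[[1]]
  idx <- as.integer(sp)
  list(path = px[idx, , drop = FALSE], r_mean = mean(ev[idx]))
}

# remove branches of <= spur_length_px pixels hanging off a junction;
# repeats until stable. px is an n x 2 matrix for one component.
prune_spurs <- function(px, spur_length_px) {
  repeat {
    g <- skeleton_graph(px)
    deg <- igraph::degree(g)
    if (length(deg) == 0L || max(deg) <= 2L) return(px)
    ends <- which(deg == 1L)
    drop <- integer(0)
    for (e in ends) {
      branch <- e; cur <- e; prev <- 0L
      repeat {
        nb <- setdiff(as.integer(igraph::neighbors(g, cur)), prev)
        if (length(nb) != 1L) break
        if (deg[nb] >= 3L) {                  # reached a junction: spur found
          if (length(branch) <= spur_length_px) drop <- c(drop, branch)
          break
        }
        if (deg[nb] == 1L) break              # endpoint-to-endpoint: main path
        branch <- c(branch, nb); prev <- cur; cur <- nb
        if (length(branch) > spur_length_px) break
      }
    }
    if (length(drop) == 0L) return(px)
    px <- px[-unique(drop), , drop = FALSE]
    if (nrow(px) == 0L) return(px)
  }
}

# longest geodesic path through one pixel set; returns ordered (y, x) matrix
longest_path <- function(px) {
  if (nrow(px) <= 1L) return(px)
  g <- skeleton_graph(px)
  idx <- as.integer(igraph::get_diameter(g, weights = igraph::E(g)$weight))
  px[idx, , drop = FALSE]
}

# decompose a binary mask into per-component centerline paths
mask_to_centerlines <- function(mask, method = c("geodesic", "thinning"),
                                spur_length_px = 4) {
  method <- match.arg(method)
  empty <- tibble(object = integer(0), path = list(), area_px = integer(0),
                  r_mean_px = numeric(0))
  if (!any(mask)) return(empty)
  if (method == "geodesic") {
    lab <- label8(mask)
    edt <- as.matrix(EBImage::distmap(mask * 1))
    n <- max(lab)
    res <- lapply(seq_len(n), function(i) {
      px <- which(lab == i, arr.ind = TRUE)
      colnames(px) <- c("y", "x")
      c(geodesic_centerline(px, edt), area = nrow(px))
    })
  } else {
    skel <- skeletonize(mask)
    lab <- label8(skel)
    n <- max(lab)
    if (n == 0L) return(empty)
    res <- lapply(seq_len(n), function(i) {
      px <- which(lab == i, arr.ind = TRUE)
      colnames(px) <- c("y", "x")
      area <- nrow(px)
      px <- prune_spurs(px, spur_length_px)
      list(path = longest_path(px), r_mean = NA_real_, area = area)
    })
  }
  keep <- vapply(res, function(r) nrow(r$path) > 0L, logical(1))
  res <- res[keep]
  tibble(object = seq_along(res),
         path = lapply(res, `[[`, "path"),
         area_px = vapply(res, function(r) as.integer(r$area), integer(1)),
         r_mean_px = vapply(res, function(r) as.numeric(r$r_mean), numeric(1)))
}
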