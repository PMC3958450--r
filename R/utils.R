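# internal helpers shared across stages

# disk structuring element: dx^2 + dy^2 <= r^2, (2r+1) x (2r+1)
disk_kernel <- function(radius) {
  d <- seq(-radius, radius)
  outer(d, d, function(y, x) as.numeric(y^2 + x^2 <= radius^2))
}

# reflect padding with edge duplication: (c b a | a b c) on each side
pad_reflect <- function(m, r) {
  ny <- nrow(m); nx <- ncol(m)
  if (r >= ny || r >= nx) stop("padding radius must be smaller than both image dimensions")
  ridx <- c(r:1, 1:ny, ny:(ny - r + 1))
  cidx <- c(r:1, 1:nx, nx:(nx - r + 1))
  m[ridx, cidx]
}

unpad <- function(m, r) {
  m[(r + 1):(nrow(m) - r), (r + 1):(ncol(m) - r), drop = FALSE]
}

# 8-connected component labeling on a logical matrix; returns integer matrix
# (EBImage::bwlabel is 4-connected, which splits diagonal skeleton steps)
label8 <- function(mask) {
  stopifnot(is.matrix(mask))
  ny <- nrow(mask); nx <- ncol(mask)
  fg <- which(mask)
  lab <- matrix(0L, ny, nx)
  if (length(fg) == 0L) return(lab)
  id <- match(seq_len(ny * nx), fg)  # pixel index -> vertex id (NA if bg)
  edges <- integer(0)
  for (d in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    yy <- arrayInd(fg, c(ny, nx))
    y2 <- yy[, 1] + d[1]; x2 <- yy[, 2] + d[2]
    ok <- y2 >= 1L & y2 <= ny & x2 >= 1L & x2 <= nx
    nb <- (x2[ok] - 1L) * ny + y2[ok]
    src <- fg[ok]
    both <- !is.na(id[nb])
    edges <- c(edges, rbind(id[src[both]], id[nb[both]]))
  }
  g <- igraph::make_graph(edges, n = length(fg), directed = FALSE)
  comp <- igraph::components(g)$membership
  # relabel components in raster order of their first pixel for determinism
  first <- tapply(seq_along(fg), comp, min)
  ord <- rank(fg[first])
  lab[fg] <- as.integer(ord[comp])
  lab
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
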