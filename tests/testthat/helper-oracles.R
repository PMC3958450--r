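# Independent oracles used across the suite. These deliberately take the
# slow, obvious route (double loops, exhaustive enumeration) so they share
# no code with the implementations they check.

# reflect-padded index (edge duplicated): ... 2 1 | 1 2 ... n | n n-1 ...
reflect_idx <- function(i, n) {
  ifelse(i < 1, 1 - i, ifelse(i > n, 2 * n + 1 - i, i))
}

# per-pixel brute-force mid-grey threshold over a disk neighborhood
oracle_midgrey <- function(frame, radius, offset = 0, min_contrast = 0) {
  ny <- nrow(frame); nx <- ncol(frame)
  out <- matrix(FALSE, ny, nx)
  offs <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  offs <- offs[offs$dy^2 + offs$dx^2 <= radius^2, ]
  for (y in seq_len(ny)) for (x in seq_len(nx)) {
    vals <- frame[cbind(reflect_idx(y + offs$dy, ny),
                        reflect_idx(x + offs$dx, nx))]
    lo <- min(vals); hi <- max(vals)
    out[y, x] <- frame[y, x] > (lo + hi) / 2 - offset &&
      (min_contrast <= 0 || hi - lo >= min_contrast)
  }
  out
}

# exhaustive minimum-cost partial matching between two centroid sets:
# matched pairs cost squared distance (only allowed within max_disp),
# unmatched objects on either side cost max_disp^2 each
oracle_match_cost <- function(prev, new, max_disp) {
  b <- max_disp^2
  na <- nrow(prev); nn <- nrow(new)
  best <- Inf
  rec <- function(i, used, cost) {
    if (cost >= best) return(invisible())
    if (i > na) {
      best <<- min(best, cost + b * (nn - sum(used)))
      return(invisible())
    }
    rec(i + 1L, used, cost + b)  # leave prev i unmatched
    for (j in seq_len(nn)) {
      if (!used[j]) {
        d2 <- sum((prev[i, ] - new[j, ])^2)
        if (d2 <= b) {
          used[j] <- TRUE
          rec(i + 1L, used, cost + d2)
          used[j] <- FALSE
        }
      }
    }
  }
  rec(1L, rep(FALSE, nn), 0)
  best
}

# total linking cost realized by link_tracks() output between consecutive
# frames, under the same objective as the oracle (memory must be 0)
realized_link_cost <- function(tracks, f1, f2, max_disp) {
  b <- max_disp^2
  a <- tracks[tracks$frame == f1, ]
  z <- tracks[tracks$frame == f2, ]
  common <- intersect(a$track, z$track)
  cost <- 0
  for (tr in common) {
    p <- a[a$track == tr, ]; q <- z[z$track == tr, ]
    cost <- cost + (p$centroid_y - q$centroid_y)^2 +
      (p$centroid_x - q$centroid_x)^2
  }
  cost + b * (nrow(a) - length(common)) + b * (nrow(z) - length(common))
}

# render a horizontal tubule of the given width into a frame, Gaussian
# blurred; used by segmentation tests that need known geometry
make_tubule_frame <- function(ny = 64, nx = 64, row = 32, x0 = 10, x1 = 54,
                              width = 4, peak = 200, bg = 10, blur = 1.5) {
  canvas <- matrix(0, ny, nx)
  half <- floor(width / 2)
  canvas[(row - half):(row + half - 1 + width %% 2), x0:x1] <- 1
  img <- bg + peak * EBImage::gblur(canvas, blur)
  round(pmin(pmax(img, 0), 255))
}
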