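#' Detect bright puncta with a multi-scale Laplacian-of-Gaussian filter
#'
#' Blob detection tuned to compact bright spots: the image is filtered with
#' scale-normalized negative-Laplacian-of-Gaussian kernels over a geometric
#' ladder of scales, local response maxima are collected across position and
#' scale, overlapping detections are suppressed (strongest first), and a
#' brightness gate keeps only peaks whose image intensity exceeds the robust
#' background level `median + k_background * MAD` of the whole frame. The
#' scale window plus the brightness gate together operationalize "larger and
#' brighter than background".
#'
#' @param image numeric Y x X matrix.
#' @param sigma_min_px,sigma_max_px Gaussian scale range (pixels) matched to
#'   the expected spot radius (sigma of approximately radius/sqrt(2)).
#' @param k_background MAD multiplier of the brightness gate (default 3).
#' @param n_scales number of scales in the ladder (default 4).
#' @param response_floor discard responses below this fraction of the
#'   strongest response (default 0.05). Candidates must also exceed six
#'   times the robust (MAD) spread of the response map, so blank or
#'   noise-only fields yield no spots.
#' @return tibble with `y`, `x`, `sigma_px`, `intensity`, `response`, one
#'   row per spot, ordered by decreasing response.
#' @export
detect_puncta <- function(image, sigma_min_px = 1, sigma_max_px = 3,
                          k_background = 3, n_scales = 4,
                          response_floor = 0.05) {
  stopifnot(is.matrix(image), sigma_min_px > 0, sigma_max_px >= sigma_min_px)
  rng <- range(image)
  empty <- tibble(y = numeric(0), x = numeric(0), sigma_px = numeric(0),
                  intensity = numeric(0), response = numeric(0))
  if (diff(rng) == 0) return(empty)
  x01 <- (image - rng[1]) / diff(rng)
  sigmas <- exp(seq(log(sigma_min_px), log(sigma_max_px),
                    length.out = n_scales))
  noise_floor <- 0
  cand <- purrr::map_dfr(seq_along(sigmas), function(k) {
    s <- sigmas[k]
    resp <- -s^2 * log_filter(x01, s)
    if (k == 1L) {
      # robust scale of the response map: local maxima of pure noise stay
      # below ~5 of these, real spots sit far above
      noise_floor <<- 6 * mad(resp)
    }
    mx <- resp == pad_max3(resp) & resp > 0
    idx <- which(mx, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(NULL)
    tibble(y = idx[, 1], x = idx[, 2], sigma_px = s,
           response = resp[idx])
  })
  if (nrow(cand) == 0L) return(empty)
  cand <- cand[cand$response >= max(response_floor * max(cand$response),
                                    noise_floor), ]
  if (nrow(cand) == 0L) return(empty)
  # non-maximum suppression across positions and scales
  cand <- dplyr::arrange(cand, dplyr::desc(.data$response))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1L) { keep[1] <- TRUE; next }
    prev <- which(keep)
    d2 <- (cand$y[prev] - cand$y[i])^2 + (cand$x[prev] - cand$x[i])^2
    rad <- pmax(cand$sigma_px[prev], cand$sigma_px[i]) * sqrt(2)
    keep[i] <- all(d2 > rad^2)
  }
  cand <- cand[keep, ]
  # brightness gate against robust background statistics
  bg_med <- median(image)
  bg_mad <- mad(image)
  cand$intensity <- image[cbind(cand$y, cand$x)]
  cand <- cand[cand$intensity > bg_med + k_background * bg_mad, ]
  dplyr::select(cand, "y", "x", "sigma_px", "intensity", "response")
}

# scale-space Laplacian: LoG response via Gaussian smoothing + discrete
# Laplacian (separable and fast; equivalent at these scales)
log_filter <- function(x, sigma) {
  g <- EBImage::gblur(x, sigma = sigma)
  shift_num(g, 1, 0) + shift_num(g, -1, 0) +
    shift_num(g, 0, 1) + shift_num(g, 0, -1) - 4 * g
}

# 3x3 neighborhood maximum (excluding nothing; ties count as maxima)
pad_max3 <- function(m) {
  out <- m
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    out <- pmax(out, shift_num(m, dy, dx))
  }
  out
}

#' Assign detected spots to labeled cell regions and count them
#'
#' Each spot is assigned to the cell region containing its center; spots on
#' the background (label 0) are discarded and counted separately. Cells with
#' no spots get count 0.
#'
#' @param spots tibble from [detect_puncta()] (columns `y`, `x`).
#' @param cell_labels integer Y x X label matrix (0 = background, cells are
#'   disjoint positive labels).
#' @return tibble with `cell`, `count`, one row per cell label; attribute
#'   `n_discarded` counts spots outside all cells.
#' @export
count_per_cell <- function(spots, cell_labels) {
  stopifnot(is.matrix(cell_labels))
  cells <- sort(unique(cell_labels[cell_labels > 0]))
  if (nrow(spots) == 0L) {
    out <- tibble(cell = as.integer(cells), count = 0L)
    attr(out, "n_discarded") <- 0L
    return(out)
  }
  lab <- cell_labels[cbind(pmin(pmax(round(spots$y), 1), nrow(cell_labels)),
                           pmin(pmax(round(spots$x), 1), ncol(cell_labels)))]
  counts <- table(factor(lab[lab > 0], levels = cells))
  out <- tibble(cell = as.integer(cells), count = as.integer(counts))
  attr(out, "n_discarded") <- sum(lab == 0)
  out
}

#' Positivity call for a per-cell puncta count
#'
#' A cell is scored positive iff it contains more than 5 puncta (strictly
#' greater; a count of exactly 5 is negative).
#'
#' @param count integer vector of per-cell counts (>= 0).
#' @return logical vector.
#' @export
classify_positive <- function(count) {
  stopifnot(all(count >= 0))
  count > 5
}

#' Autophagy index of a field
#'
#' The mean number of puncta per cell.
#'
#' @param counts integer vector of per-cell counts (>= 1 cell).
#' @return mean puncta per cell.
#' @export
autophagy_index <- function(counts) {
  if (length(counts) < 1L) stop("need at least one cell")
  mean(counts)
}

#' Fold change between two autophagy indices
#'
#' @param index_a numerator condition.
#' @param index_b denominator condition (> 0).
#' @return `index_a / index_b`.
#' @export
fold_change <- function(index_a, index_b) {
  if (index_b <= 0) stop("denominator index must be positive")
  index_a / index_b
}

#' Full per-field puncta scoring
#'
#' Chains [detect_puncta()], [count_per_cell()], [classify_positive()] and
#' [autophagy_index()] on one field.
#'
#' @param image numeric Y x X matrix.
#' @param cell_labels integer label matrix of cell regions.
#' @param ... passed to [detect_puncta()].
#' @return object of class `puncta_result`: list with `cells` (tibble
#'   `cell`, `count`, `positive`), `n_cells`, `fraction_positive_pct`,
#'   `autophagy_index`, `n_discarded`.
#' @export
analyze_puncta <- function(image, cell_labels, ...) {
  spots <- detect_puncta(image, ...)
  counts <- count_per_cell(spots, cell_labels)
  cells <- dplyr::mutate(counts, positive = classify_positive(.data$count))
  structure(
    list(cells = cells,
         n_cells = nrow(cells),
         fraction_positive_pct = 100 * mean(cells$positive),
         autophagy_index = autophagy_index(cells$count),
         n_discarded = attr(counts, "n_discarded")),
    class = "puncta_result")
}

#' @export
print.puncta_result <- function(x, ...) {
  cat(sprintf(
    "<puncta_result> %d cells, %.1f%% positive (>5 puncta), autophagy index %.2f\n",
    x$n_cells, x$fraction_positive_pct, x$autophagy_index))
  invisible(x)
}

#' One-row summary of a puncta analysis
#' @param x a `puncta_result`.
#' @param ... unused.
#' @return one-row tibble.
#' @export
glance.puncta_result <- function(x, ...) {
  tibble(n_cells = x$n_cells,
         fraction_positive_pct = x$fraction_positive_pct,
         autophagy_index = x$autophagy_index,
         n_discarded = x$n_discarded)
}
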