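#' Dynamic range of a length time series
#'
#' The per-object statistic for length remodelling activity:
#' `100 * (max - min) / mean` of the series, in percent. A constant series
#' has dynamic range 0; a series oscillating between half and twice its mean
#' has dynamic range far above 100. The statistic is invariant under
#' rescaling of the series, so it is insensitive to calibration.
#'
#' @param length_series numeric vector of per-frame lengths (>= 2 finite,
#'   positive values).
#' @return percent, >= 0.
#' @export
dynamic_range <- function(length_series) {
  x <- length_series[is.finite(length_series)]
  if (length(x) < 2L) stop("need at least 2 finite values")
  if (any(x <= 0) || mean(x) <= 0) stop("lengths must be positive")
  100 * (max(x) - min(x)) / mean(x)
}

track_xy <- function(track) {
  stopifnot(is.data.frame(track),
            all(c("centroid_y", "centroid_x") %in% names(track)))
  if ("frame" %in% names(track)) track <- dplyr::arrange(track, .data$frame)
  cbind(track$centroid_y, track$centroid_x)
}

#' Net displacement of a track
#'
#' Euclidean distance between the first and last centroid, in microns.
#'
#' @param track per-track tibble with `centroid_y`, `centroid_x` (ordered by
#'   `frame` if present).
#' @param pixel_size_um microns per pixel.
#' @return microns.
#' @export
net_displacement <- function(track, pixel_size_um) {
  p <- track_xy(track)
  if (nrow(p) < 2L) stop("need at least 2 records")
  sqrt(sum((p[nrow(p), ] - p[1, ])^2)) * pixel_size_um
}

#' Path length of a track
#'
#' Sum of consecutive centroid step distances, in microns. Always at least
#' the net displacement.
#'
#' @inheritParams net_displacement
#' @return microns.
#' @export
path_length <- function(track, pixel_size_um) {
  p <- track_xy(track)
  if (nrow(p) < 2L) stop("need at least 2 records")
  sum(sqrt(rowSums(diff(p)^2))) * pixel_size_um
}

#' Directionality (confinement ratio) of a track
#'
#' Net displacement divided by path length: 1 for straight monotone motion,
#' 0 for a closed loop, intermediate for meandering movement.
#'
#' @inheritParams net_displacement
#' @return ratio in `[0, 1]`.
#' @export
directionality <- function(track) {
  p <- track_xy(track)
  if (nrow(p) < 2L) stop("need at least 2 records")
  pl <- sum(sqrt(rowSums(diff(p)^2)))
  if (pl <= 0) stop("path length is zero")
  sqrt(sum((p[nrow(p), ] - p[1, ])^2)) / pl
}

#' Summarise per-track morphology dynamics
#'
#' Computes, for every track with at least `min_track_len` records, the mean
#' length, dynamic range, net displacement, path length and directionality,
#' plus condition-level medians and interquartile ranges. Medians/IQRs are
#' used (rather than means) because track lengths are heterogeneous and the
#' per-track statistics are skewed.
#'
#' @param tracks output of [link_tracks()]: tibble with `track`, `frame`,
#'   `length_um`, `centroid_y`, `centroid_x`.
#' @param pixel_size_um microns per pixel.
#' @param min_track_len minimum records per track (default 3); shorter
#'   tracks are excluded and counted in `n_excluded`.
#' @return an object of class `dynamics_summary` with elements `tracks`
#'   (per-track tibble), `condition` (one-row tibble of medians and IQRs),
#'   `n_excluded`, `pixel_size_um`. [tidy()][generics::tidy] returns the
#'   per-track table, [glance()][generics::glance] the condition row.
#' @export
summarize_dynamics <- function(tracks, pixel_size_um, min_track_len = 3) {
  stopifnot(is.data.frame(tracks),
            all(c("track", "frame", "length_um", "centroid_y", "centroid_x")
                %in% names(tracks)))
  per <- tracks |>
    dplyr::group_by(.data$track) |>
    dplyr::group_split()
  sizes <- vapply(per, nrow, integer(1))
  n_excluded <- sum(sizes < min_track_len)
  per <- per[sizes >= min_track_len]
  if (length(per) == 0L) stop("no tracks with >= ", min_track_len, " records")
  tr <- purrr::map_dfr(per, function(d) {
    d <- dplyr::arrange(d, .data$frame)
    const <- all(abs(d$length_um - d$length_um[1]) < 1e-12)
    still <- path_length(d, pixel_size_um) <= 0
    tibble(
      track = d$track[1],
      n_frames = nrow(d),
      mean_length_um = mean(d$length_um),
      dynamic_range_pct = if (const) 0 else dynamic_range(d$length_um),
      net_displacement_um = net_displacement(d, pixel_size_um),
      path_length_um = path_length(d, pixel_size_um),
      directionality = if (still) 0 else directionality(d)
    )
  })
  metrics <- c("mean_length_um", "dynamic_range_pct", "net_displacement_um",
               "path_length_um", "directionality")
  cond <- dplyr::bind_cols(
    tibble(n_tracks = nrow(tr), n_excluded = n_excluded),
    tibble::as_tibble_row(setNames(
      lapply(metrics, function(m) median(tr[[m]])),
      paste0("median_", m_short(metrics)))),
    tibble::as_tibble_row(setNames(
      lapply(metrics, function(m) stats::IQR(tr[[m]])),
      paste0("iqr_", m_short(metrics))))
  )
  structure(list(tracks = tr, condition = cond, n_excluded = n_excluded,
                 pixel_size_um = pixel_size_um),
            class = "dynamics_summary")
}

m_short <- function(x) sub("_(um|pct)$", "", x)

#' @export
print.dynamics_summary <- function(x, ...) {
  cat(sprintf("<dynamics_summary> %d track(s), %d excluded (< min length)\n",
              nrow(x$tracks), x$n_excluded))
  cat(sprintf("  median dynamic range: %.1f%%  median length: %.2f um\n",
              x$condition$median_dynamic_range, x$condition$median_mean_length))
  invisible(x)
}

#' Tidy a dynamics summary into its per-track table
#' @param x a `dynamics_summary`.
#' @param ... unused.
#' @return per-track tibble.
#' @export
tidy.dynamics_summary <- function(x, ...) x$tracks

#' One-row condition-level summary of a dynamics fit
#' @param x a `dynamics_summary`.
#' @param ... unused.
#' @return one-row tibble of medians and IQRs.
#' @export
glance.dynamics_summary <- function(x, ...) x$condition
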