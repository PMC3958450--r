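#' Per-frame object records from centerlines
#'
#' Computes each centerline's centroid (the unweighted mean of its path pixel
#' coordinates) and returns the per-object record table used by the tracker.
#' [segment_movie()] already produces these columns; this helper exists for
#' centerline tables built elsewhere.
#'
#' @param centerlines tibble with a `path` list column (and optionally
#'   `frame`, `object`).
#' @return the input with `centroid_y`, `centroid_x` columns added.
#' @export
centroids <- function(centerlines) {
  stopifnot(is.data.frame(centerlines), "path" %in% names(centerlines))
  dplyr::mutate(centerlines,
    centroid_y = vapply(.data$path, function(p) mean(p[, 1]), numeric(1)),
    centroid_x = vapply(.data$path, function(p) mean(p[, 2]), numeric(1)))
}

#' Link per-frame records into tracks
#'
#' Links objects across frames by optimal bipartite assignment on squared
#' centroid displacement (Hungarian algorithm), in the Crocker-Grier
#' formulation: candidate matches farther than `max_disp_px` are forbidden,
#' and leaving an object unmatched costs `max_disp_px^2`, so the assignment
#' trades off displacement against track termination/initiation. Objects
#' that vanish may reappear within `memory_frames` frames and continue their
#' track (a gap); otherwise the track closes and a reappearing object starts
#' a new one. Ties between equal-cost assignments break toward the lowest
#' previous-object index.
#'
#' @param records tibble with columns `frame`, `centroid_y`, `centroid_x`
#'   (plus any others, carried through), one row per object per frame.
#' @param max_disp_px maximum centroid displacement per frame step, pixels.
#' @param memory_frames frames an object may be missing and still be
#'   reclaimed by its track.
#' @return the input tibble with a `track` column added, ordered by track
#'   then frame; attribute `n_tracks` gives the track count.
#' @export
link_tracks <- function(records, max_disp_px = 20, memory_frames = 2) {
  stopifnot(is.data.frame(records),
            all(c("frame", "centroid_y", "centroid_x") %in% names(records)))
  if (max_disp_px <= 0) stop("max_disp_px must be positive")
  if (memory_frames < 0) stop("memory_frames must be >= 0")
  records <- dplyr::arrange(records, .data$frame)
  n <- nrow(records)
  track_of <- integer(n)
  if (n == 0L) return(dplyr::mutate(records, track = integer(0)))

  frames <- sort(unique(records$frame))
  next_track <- 1L
  # active tracks: row indices into records of each track's last record
  active <- integer(0)
  for (f in frames) {
    rows <- which(records$frame == f)
    # close tracks whose last record is too old to bridge the gap
    if (length(active)) {
      age_ok <- f - records$frame[active] <= memory_frames + 1L
      active <- active[age_ok]
    }
    if (length(active) == 0L) {
      track_of[rows] <- seq.int(next_track, length.out = length(rows))
      next_track <- next_track + length(rows)
      active <- rows
      next
    }
    assign <- match_frame(
      cbind(records$centroid_y[active], records$centroid_x[active]),
      cbind(records$centroid_y[rows], records$centroid_x[rows]),
      max_disp_px)
    matched_new <- !is.na(assign)
    track_of[rows[assign[matched_new]]] <- track_of[active[matched_new]]
    new_rows <- rows[setdiff(seq_along(rows), assign[matched_new])]
    if (length(new_rows)) {
      track_of[new_rows] <- seq.int(next_track, length.out = length(new_rows))
      next_track <- next_track + length(new_rows)
    }
    active <- c(active[!matched_new], rows)
  }
  out <- dplyr::mutate(records, track = track_of)
  out <- dplyr::arrange(out, .data$track, .data$frame)
  attr(out, "n_tracks") <- next_track - 1L
  out
}

# Optimal assignment of previous centroids (rows of `prev`) to new centroids
# (rows of `new`), squared-distance cost, birth/death cost = max_disp^2,
# pairs beyond max_disp forbidden. Returns, for each prev row, the index of
# the matched new row or NA. The augmented square matrix [C d; d 0] is the
# standard LAP encoding of matching-with-opt-out.
match_frame <- function(prev, new, max_disp) {
  na <- nrow(prev); nn <- nrow(new)
  b <- max_disp^2
  big <- 4 * b * (na + nn + 1)  # prohibitive, but finite for the LAP solver
  C <- outer(seq_len(na), seq_len(nn), function(i, j) {
    (prev[i, 1] - new[j, 1])^2 + (prev[i, 2] - new[j, 2])^2
  })
  C[C > b] <- big
  # infinitesimal lexicographic perturbation: equal-cost optima resolve
  # toward low previous-object indices matched to low new indices
  eps <- b * 1e-9
  P <- outer(seq_len(na), seq_len(nn), function(i, j) (i * (nn + 1) + j) * eps)
  M <- matrix(big, na + nn, na + nn)
  M[seq_len(na), seq_len(nn)] <- C + P
  for (i in seq_len(na)) M[i, nn + i] <- b        # death of prev i
  for (j in seq_len(nn)) M[na + j, j] <- b        # birth of new j
  M[(na + 1):(na + nn), (nn + 1):(nn + na)] <- 0  # dummy-dummy
  sol <- as.integer(clue::solve_LSAP(M))
  out <- rep(NA_integer_, na)
  real <- sol[seq_len(na)]
  ok <- real <= nn & M[cbind(seq_len(na), real)] < big
  out[ok] <- real[ok]
  out
}

#' Gap counts per track
#'
#' @param tracks output of [link_tracks()].
#' @return tibble with `track`, `n_records`, `n_gaps` (frames skipped inside
#'   the track).
#' @export
track_gaps <- function(tracks) {
  stopifnot(all(c("track", "frame") %in% names(tracks)))
  dplyr::summarise(dplyr::group_by(tracks, .data$track),
    n_records = dplyr::n(),
    n_gaps = sum(pmax(diff(.data$frame) - 1L, 0L)),
    .groups = "drop")
}
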