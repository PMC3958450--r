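#' Adaptive local mid-grey threshold
#'
#' Binarizes a frame against the mid-grey of its local neighborhood: a pixel
#' is foreground iff its intensity strictly exceeds
#' `(local_min + local_max) / 2 - offset`, where the local extrema are taken
#' over a disk of the given radius centred on the pixel. This is the standard
#' adaptive local threshold for unevenly illuminated fluorescence frames
#' containing compact bright objects. Borders are handled by reflect padding.
#' Ties go to background, so a constant image yields an empty mask.
#'
#' In neighborhoods containing no object the mid-grey sits in the middle of
#' the noise and roughly half of the background pixels would come out
#' foreground (the classic flat-region failure of adaptive thresholds).
#' `min_contrast` guards against this: pixels whose local contrast
#' (`local_max - local_min`) is below it are forced to background. The
#' default 0 applies the pure mid-grey rule; the pipeline uses a positive
#' guard (see [segment_movie()]).
#'
#' @param frame numeric Y x X intensity matrix.
#' @param radius neighborhood disk radius in pixels (default 15).
#' @param offset subtracted from the mid-grey before comparison; positive
#'   values make segmentation more permissive.
#' @param min_contrast minimum local max-min contrast for a pixel to be
#'   eligible as foreground (default 0 = no guard).
#' @return logical Y x X mask with attributes `method`, `radius`, `offset`.
#' @export
midgrey_threshold <- function(frame, radius = 15, offset = 0,
                              min_contrast = 0) {
  stopifnot(is.matrix(frame), is.numeric(frame))
  if (!is_count(radius) || radius < 1) stop("radius must be a positive integer")
  if (radius > nrow(frame) || radius > ncol(frame))
    stop("radius larger than an image dimension")
  k <- disk_kernel(radius)
  p <- pad_reflect(frame, radius)
  # EBImage grayscale morphology operates on [0, 1]; rescale around it
  top <- max(p, 1)
  lo <- unpad(EBImage::erode(p / top, k), radius) * top
  hi <- unpad(EBImage::dilate(p / top, k), radius) * top
  mask <- frame > (lo + hi) / 2 - offset
  if (min_contrast > 0) mask <- mask & (hi - lo) >= min_contrast
  structure(mask, method = "midgrey", radius = radius, offset = offset)
}

#' Remove small connected components from a mask
#'
#' Connected components (8-connectivity) with fewer than `min_area_px` pixels
#' are removed; everything else is untouched. The default suppresses specks
#' smaller than a 3 x 3 block, below the optical resolution at 0.09 um/px.
#'
#' @param mask logical Y x X matrix.
#' @param min_area_px minimum component area to keep (>= 0).
#' @return logical mask of the same shape.
#' @export
clean_mask <- function(mask, min_area_px = 9) {
  stopifnot(is.matrix(mask), min_area_px >= 0)
  if (min_area_px <= 1 || !any(mask)) return(mask)
  lab <- label8(mask)
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= min_area_px)
  out <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  attributes(out) <- attributes(mask)
  dim(out) <- dim(mask)
  out
}

#' Extract single-pixel-wide centerlines from a binary mask
#'
#' Reduces every connected component (8-connectivity) of the mask to an
#' ordered single-pixel-wide centerline path. The default `"geodesic"`
#' method follows the ridge of the Euclidean distance transform (the medial
#' axis) between the component's two most distant pixels, so the path spans
#' the object tip to tip; the returned `r_mean_px` (mean distance-transform
#' value along the path, i.e. the tube half-width) supports end-cap length
#' correction downstream. The `"thinning"` method is classic iterative
#' (Zhang-Suen) thinning with pruning of side branches shorter than
#' `spur_length_px` and reduction to the longest geodesic path; it retracts
#' rounded tubule ends by roughly the tube width, so prefer `"geodesic"`
#' whenever lengths matter.
#'
#' @param mask logical Y x X matrix.
#' @param method `"geodesic"` (distance-transform medial axis, default) or
#'   `"thinning"` (Zhang-Suen).
#' @param spur_length_px prune skeleton branches of at most this many pixels
#'   that hang off a junction (`"thinning"` only; default 4).
#' @return tibble with one row per object: `object`, `path` (list column of
#'   ordered n x 2 `(y, x)` pixel matrices), `area_px` (component pixel
#'   count), `r_mean_px` (mean tube half-width along the path; `NA` for
#'   `"thinning"`). An empty mask yields zero rows.
#' @export
medial_axis_centerlines <- function(mask, method = c("geodesic", "thinning"),
                                    spur_length_px = 4) {
  stopifnot(is.matrix(mask))
  mask_to_centerlines(mask, method = method, spur_length_px = spur_length_px)
}

#' Trace centerlines of bright tubular structures by Hessian ridge filtering
#'
#' Computes a scale-normalized ridge-strength map from the principal
#' curvature of the Gaussian-smoothed image's Hessian (bright tubules produce
#' a strongly negative second derivative across the tube), thresholds it,
#' and skeletonizes the resulting mask into centerline paths. Intended for
#' bright, interconnected tubular networks where a local intensity threshold
#' alone merges or misses tubules.
#'
#' @param frame numeric Y x X intensity matrix.
#' @param tubule_sigma_px Gaussian scale matched to the tubule half-width in
#'   pixels (> 0; default 2).
#' @param response_threshold ridge-strength cutoff on the scale-normalized
#'   response of the intensity-normalized (0-1) image (default 0.04).
#' @param min_area_px drop ridge components smaller than this (default 9).
#' @return tibble of centerlines as in [medial_axis_centerlines()].
#' @export
ridge_centerlines <- function(frame, tubule_sigma_px = 2,
                              response_threshold = 0.04,
                              min_area_px = 9) {
  stopifnot(is.matrix(frame), is.numeric(frame))
  if (tubule_sigma_px <= 0) stop("tubule_sigma_px must be positive")
  rng <- range(frame)
  if (diff(rng) == 0) {
    return(tibble(object = integer(0), path = list(), area_px = integer(0),
                  r_mean_px = numeric(0)))
  }
  x <- (frame - rng[1]) / diff(rng)
  g <- EBImage::gblur(x, sigma = tubule_sigma_px)
  gy <- (shift_num(g, 1, 0) - shift_num(g, -1, 0)) / 2
  gx <- (shift_num(g, 0, 1) - shift_num(g, 0, -1)) / 2
  gyy <- shift_num(g, 1, 0) + shift_num(g, -1, 0) - 2 * g
  gxx <- shift_num(g, 0, 1) + shift_num(g, 0, -1) - 2 * g
  gxy <- (shift_num(gy, 0, 1) - shift_num(gy, 0, -1)) / 2
  # smaller Hessian eigenvalue; strongly negative across a bright ridge
  lam <- ((gxx + gyy) - sqrt((gxx - gyy)^2 + 4 * gxy^2)) / 2
  ridge <- pmax(-lam, 0) * tubule_sigma_px^2
  mask <- clean_mask(ridge > response_threshold, min_area_px)
  mask_to_centerlines(mask, method = "geodesic")
}

# trim a centerline path to its full-width-half-maximum endpoints: drop
# leading/trailing pixels whose background-subtracted intensity is below
# half the along-path median
trim_halfmax <- function(path, frame) {
  if (nrow(path) < 3L) return(path)
  i <- frame[path] - median(frame)
  plateau <- median(i)
  if (plateau <= 0) return(path)
  keep <- which(i >= 0.5 * plateau)
  if (length(keep) < 2L) return(path)
  path[min(keep):max(keep), , drop = FALSE]
}

# like shift_mat but replicates the border row/column (for derivatives)
shift_num <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  ys <- pmin(pmax(seq_len(ny) + dy, 1L), ny)
  xs <- pmin(pmax(seq_len(nx) + dx, 1L), nx)
  m[ys, xs, drop = FALSE]
}

#' Geodesic length of a centerline path
#'
#' Sums the per-step lengths along the ordered pixel path (1 for an axial
#' step, sqrt(2) for a diagonal step) and scales by the pixel size. A single
#' pixel has length 0.
#'
#' @param path ordered n x 2 `(y, x)` pixel matrix, as stored in the `path`
#'   column returned by the centerline extractors.
#' @param pixel_size_um microns per pixel.
#' @return length in microns.
#' @export
measure_length <- function(path, pixel_size_um) {
  if (is.null(path) || nrow(path) == 0L) stop("empty centerline")
  stopifnot(pixel_size_um > 0)
  if (nrow(path) == 1L) return(0)
  steps <- sqrt(diff(path[, 1])^2 + diff(path[, 2])^2)
  sum(steps) * pixel_size_um
}

#' Segment every frame of a movie into measured centerlines
#'
#' Runs the chosen per-frame segmentation (`"midgrey"`: adaptive local
#' threshold + medial-axis centerline extraction, for fragmented
#' morphologies; `"ridge"`: Hessian ridge tracing, for bright tubular
#' networks), measures each object's centerline length and centroid, and
#' returns one tidy table for the whole movie.
#'
#' Because the centerline path spans the segmented object tip to tip, the
#' reported `length_um` removes the end caps that segmentation adds beyond
#' the true filament ends. In `"midgrey"` mode the mask boundary is already
#' an (adaptive) half-maximum surface, so the path is simply shortened by
#' the mean tube half-width (`r_mean_px`) at each end — the radius of the
#' rounded cap. In `"ridge"` mode the mask extent is set by the curvature
#' response, which overshoots the filament tip, so the path is first
#' trimmed to where the background-subtracted intensity falls below half of
#' its along-path median (the full-width-half-maximum endpoints) and then
#' shortened by the same cap radii. Set `cap_correction = FALSE` for raw
#' tip-to-tip path lengths.
#'
#' @param x a [movie()].
#' @param mode `"midgrey"` or `"ridge"`.
#' @param radius,offset,min_contrast,min_area_px mid-grey parameters (see
#'   [midgrey_threshold()], [clean_mask()]); `min_contrast` defaults to 25
#'   (10% of the 8-bit range) here, which suppresses object-free background
#'   while leaving any neighborhood containing a bright object untouched.
#' @param tubule_sigma_px,response_threshold ridge parameters (see
#'   [ridge_centerlines()]).
#' @param cap_correction correct measured lengths for segmentation end caps
#'   (default `TRUE`; see Details).
#' @return tibble with columns `frame`, `object`, `length_um`, `centroid_y`,
#'   `centroid_x`, `n_px`, `r_mean_px`, `path` (list column).
#' @export
segment_movie <- function(x, mode = c("midgrey", "ridge"),
                          radius = 15, offset = 0, min_contrast = 25,
                          min_area_px = 9,
                          tubule_sigma_px = 2, response_threshold = 0.04,
                          cap_correction = TRUE) {
  stopifnot(inherits(x, "mito_movie"))
  mode <- match.arg(mode)
  res <- purrr::map(seq_along(x$frames), function(i) {
    cl <- switch(mode,
      midgrey = {
        m <- clean_mask(midgrey_threshold(x$frames[[i]], radius, offset,
                                          min_contrast),
                        min_area_px)
        medial_axis_centerlines(m)
      },
      ridge = ridge_centerlines(x$frames[[i]], tubule_sigma_px,
                                response_threshold, min_area_px)
    )
    if (nrow(cl) == 0L) return(NULL)
    if (mode == "ridge" && cap_correction) {
      cl$path <- lapply(cl$path, trim_halfmax, frame = x$frames[[i]])
    }
    dplyr::mutate(cl, frame = i)
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) {
    return(tibble(frame = integer(0), object = integer(0),
                  length_um = numeric(0), centroid_y = numeric(0),
                  centroid_x = numeric(0), n_px = integer(0),
                  r_mean_px = numeric(0), path = list()))
  }
  raw_px <- vapply(out$path, function(p) {
    if (nrow(p) < 2L) 0 else measure_length(p, 1)
  }, numeric(1))
  cap_px <- if (cap_correction) {
    ifelse(is.finite(out$r_mean_px), 2 * out$r_mean_px, 0)
  } else 0
  out <- dplyr::mutate(out,
    length_um = pmax(raw_px - cap_px, 0) * x$pixel_size_um,
    centroid_y = vapply(.data$path, function(p) mean(p[, 1]), numeric(1)),
    centroid_x = vapply(.data$path, function(p) mean(p[, 2]), numeric(1)),
    n_px = vapply(.data$path, nrow, integer(1))
  )
  dplyr::select(out, "frame", "object", "length_um", "centroid_y",
                "centroid_x", "n_px", "r_mean_px", "path")
}
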