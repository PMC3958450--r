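#' Calibrated image time series
#'
#' A movie couples a list of grayscale intensity frames with its spatial and
#' temporal calibration. Frames are numeric matrices indexed `[row, column]`
#' (y, x), 1-based, with intensities in native units (0-255 for 8-bit data).
#'
#' @param frames list of numeric Y x X matrices (one per time point), or a
#'   single matrix, or a Y x X x T array.
#' @param pixel_size_um microns per pixel (must be > 0).
#' @param time_step_s seconds between consecutive frames (must be > 0).
#' @return An object of class `mito_movie`: a list with elements `frames`,
#'   `pixel_size_um`, `time_step_s`.
#' @examples
#' mv <- movie(matrix(0, 16, 16), pixel_size_um = 0.09, time_step_s = 109)
#' n_frames(mv)
#' @export
movie <- function(frames, pixel_size_um = 0.09, time_step_s = 109) {
  if (is.matrix(frames)) frames <- list(frames)
  if (is.array(frames) && length(dim(frames)) == 3L) {
    frames <- lapply(seq_len(dim(frames)[3]), function(t) frames[, , t])
  }
  stopifnot(is.list(frames), length(frames) >= 1L)
  dims <- vapply(frames, dim, integer(2))
  if (!all(dims[1, ] == dims[1, 1]) || !all(dims[2, ] == dims[2, 1]))
    stop("all frames must share the same dimensions")
  if (any(vapply(frames, function(f) any(f < 0), logical(1))))
    stop("intensities must be non-negative")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be positive")
  if (!is.numeric(time_step_s) || time_step_s <= 0)
    stop("time_step_s must be positive")
  structure(
    list(frames = frames, pixel_size_um = pixel_size_um,
         time_step_s = time_step_s),
    class = "mito_movie"
  )
}

#' @export
print.mito_movie <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<mito_movie> %d frame(s), %d x %d px, %.3g um/px, %.4g s/frame\n",
              length(x$frames), d[1], d[2], x$pixel_size_um, x$time_step_s))
  invisible(x)
}

#' @rdname movie
#' @param x a `mito_movie`.
#' @export
n_frames <- function(x) length(x$frames)

#' Read a grayscale TIFF stack as a calibrated movie
#'
#' Reads a single- or multi-page grayscale TIFF. Intensities are returned in
#' native integer units (0-255 for 8-bit, 0-65535 for 16-bit). Calibration is
#' taken from the arguments; when an argument is `NULL` the TIFF X-resolution
#' tag is consulted (arguments win), and failing that the package defaults
#' (0.09 um/px, 109 s/frame) are used with a message.
#'
#' @param path path to a TIFF file.
#' @param pixel_size_um,time_step_s calibration; `NULL` to fall back to
#'   metadata / defaults.
#' @param rgb_to_gray if `TRUE`, RGB pages are converted to luminance
#'   averages; if `FALSE` (default) RGB input is an error.
#' @return a [movie()].
#' @export
read_stack <- function(path, pixel_size_um = NULL, time_step_s = NULL,
                       rgb_to_gray = FALSE) {
  if (!file.exists(path)) stop("cannot read TIFF: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (!rgb_to_gray)
        stop("RGB TIFF; pass rgb_to_gray = TRUE to convert to grayscale")
      apply(p, c(1, 2), mean)
    } else p
  })
  if (is.null(pixel_size_um)) {
    xres <- attr(pages[[1]], "x.resolution")
    if (!is.null(xres) && is.finite(xres) && xres > 0) {
      pixel_size_um <- 1 / xres  # resolution stored as pixels per micron
    } else {
      message("no pixel size in arguments or metadata; using 0.09 um/px")
      pixel_size_um <- 0.09
    }
  }
  if (is.null(time_step_s)) {
    message("no time step supplied; using 109 s/frame")
    time_step_s <- 109
  }
  movie(frames, pixel_size_um = pixel_size_um, time_step_s = time_step_s)
}

#' Write a movie as a multi-page grayscale TIFF
#'
#' Intensities are stored at the requested bit depth; values must lie in
#' `[0, 2^bits - 1]` and are written without rescaling, so a
#' [read_stack()]/[write_stack()] round trip is bit-exact for integer data.
#' Calibration is not stored in the file; keep it in the run configuration.
#'
#' @param x a [movie()].
#' @param path output path.
#' @param bits bits per sample (8 or 16).
#' @return `path`, invisibly.
#' @export
write_stack <- function(x, path, bits = 8) {
  stopifnot(inherits(x, "mito_movie"), bits %in% c(8, 16))
  top <- 2^bits - 1
  if (any(vapply(x$frames, function(f) any(f > top), logical(1))))
    stop("intensities exceed ", bits, "-bit range")
  tiff::writeTIFF(lapply(x$frames, function(f) f / top), path,
                  bits.per.sample = bits, reduce = TRUE)
  invisible(path)
}

#' Pick the best-in-focus plane of a z-stack
#'
#' Scores each plane by the variance of its Laplacian response (a standard
#' autofocus criterion: in-focus planes have the strongest second-derivative
#' texture) and returns the index of the maximum. Ties break to the first
#' index, so a stack of identical planes returns 1.
#'
#' @param z_stack list of Y x X matrices or a Y x X x Z array.
#' @return integer plane index (1-based).
#' @export
best_focus_plane <- function(z_stack) {
  if (is.array(z_stack) && length(dim(z_stack)) == 3L)
    z_stack <- lapply(seq_len(dim(z_stack)[3]), function(z) z_stack[, , z])
  if (is.matrix(z_stack)) z_stack <- list(z_stack)
  if (length(z_stack) == 0L) stop("empty z-stack")
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  score <- vapply(z_stack, function(p) {
    var(as.vector(EBImage::filter2(p, lap, boundary = "replicate")))
  }, numeric(1))
  which.max(score)
}

#' Rectangular region of interest
#'
#' Rectangles are axis-aligned, 1-based and inclusive: a ROI covers rows
#' `y0 ... y0 + height - 1` and columns `x0 ... x0 + width - 1`.
#'
#' @param x0,y0 top-left corner (column, row), 1-based.
#' @param width,height extent in pixels (>= 1).
#' @param label optional name.
#' @return a one-row tibble of class `mito_roi`.
#' @export
roi <- function(x0, y0, width, height, label = NA_character_) {
  stopifnot(is_count(x0), is_count(y0), is_count(width), is_count(height),
            x0 >= 1, y0 >= 1, width >= 1, height >= 1)
  structure(
    tibble(x0 = as.integer(x0), y0 = as.integer(y0),
           width = as.integer(width), height = as.integer(height),
           label = label),
    class = c("mito_roi", "tbl_df", "tbl", "data.frame")
  )
}

roi_check <- function(r, dim_yx) {
  if (r$y0 + r$height - 1L > dim_yx[1] || r$x0 + r$width - 1L > dim_yx[2])
    stop("ROI exceeds frame bounds (", dim_yx[1], " x ", dim_yx[2], " px)")
  invisible(r)
}

#' Crop a movie to a region of interest
#'
#' @param x a [movie()].
#' @param r a [roi()].
#' @return the cropped [movie()]; calibration is preserved.
#' @export
crop_movie <- function(x, r) {
  stopifnot(inherits(x, "mito_movie"))
  roi_check(r, dim(x$frames[[1]]))
  rows <- r$y0:(r$y0 + r$height - 1L)
  cols <- r$x0:(r$x0 + r$width - 1L)
  movie(lapply(x$frames, function(f) f[rows, cols, drop = FALSE]),
        pixel_size_um = x$pixel_size_um, time_step_s = x$time_step_s)
}

#' Read a pipeline run configuration from YAML
#'
#' The configuration carries the input source (a file path with calibration,
#' or a synthetic preset), stage parameters, ROIs and the output directory.
#' See `vignette("mitodyn-methods")` for the schema.
#'
#' @param path YAML file.
#' @return a named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$input)) stop("config must have an 'input' block")
  has_path <- !is.null(cfg$input$path)
  has_preset <- !is.null(cfg$input$preset)
  if (has_path == has_preset)
    stop("config input must have exactly one of 'path' or 'preset'")
  if (has_path && !file.exists(cfg$input$path))
    stop("input file does not exist: ", cfg$input$path)
  cfg
}
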