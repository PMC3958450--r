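#' Shipped simulation presets for mitochondrial movies
#'
#' Two presets encode the two imaged conditions: `"control_mito"` emulates a
#' tubular network of long filaments (5-10 um) with large length dynamics
#' (dynamic range 1.0, i.e. (max-min)/mean of the per-frame length series),
#' and `"mutant_mito"` emulates fragmented mitochondria (1-3 um) whose
#' length dynamics are largely arrested (dynamic range 0.15). Geometry and
#' calibration follow the acquisition emulated throughout the package:
#' 0.09 um/pixel, 109 s/frame, 8-bit intensities.
#'
#' @param name `"control_mito"` or `"mutant_mito"`, or a list with the same
#'   fields to define a custom preset.
#' @return a list of class `mito_preset` with fields `name`, `n_objects`,
#'   `length_range_um`, `tubule_width_um`, `osc_amplitude` (relative
#'   (max-min)/mean of the true length series), `jitter_um` (per-frame
#'   centroid step SD), `event_rate` (fission probability per object per
#'   frame), `psf_sigma_um`, `noise_sigma` (additive Gaussian SD, intensity
#'   units), `poisson_noise`, `background`, `peak_intensity`, `field_px`,
#'   `pixel_size_um`, `time_step_s`.
#' @export
mito_preset <- function(name = c("control_mito", "mutant_mito")) {
  if (is.list(name)) return(structure(name, class = "mito_preset"))
  name <- match.arg(name)
  base <- list(
    name = name, tubule_width_um = 0.36, event_rate = 0,
    psf_sigma_um = 0.15, noise_sigma = 2, poisson_noise = FALSE,
    background = 12, peak_intensity = 200,
    pixel_size_um = 0.09, time_step_s = 109
  )
  cond <- switch(name,
    control_mito = list(n_objects = 6, length_range_um = c(5, 10),
                        osc_amplitude = 1.0, jitter_um = 0.15,
                        field_px = 512),
    mutant_mito = list(n_objects = 12, length_range_um = c(1, 3),
                       osc_amplitude = 0.15, jitter_um = 0.05,
                       field_px = 288)
  )
  structure(c(base, cond), class = "mito_preset")
}

# smooth random open curve of target arc length (px), 1-px steps:
# heading performs a bounded random walk, giving gently wiggling filaments
random_curve <- function(length_px, field_px, margin) {
  n <- max(2L, round(length_px))
  theta0 <- runif(1, 0, 2 * pi)
  dtheta <- rnorm(n - 1, 0, 0.06)
  theta <- theta0 + cumsum(c(0, dtheta[-1]))
  y <- cumsum(c(0, sin(theta)))
  x <- cumsum(c(0, cos(theta)))
  # center in a random in-bounds window
  ylim <- range(y); xlim <- range(x)
  if (diff(ylim) > field_px - 2 * margin || diff(xlim) > field_px - 2 * margin)
    return(NULL)
  y0 <- runif(1, margin - ylim[1], field_px - margin - ylim[2])
  x0 <- runif(1, margin - xlim[1], field_px - margin - xlim[2])
  cbind(y = y + y0, x = x + x0)
}

polyline_length <- function(p) sum(sqrt(rowSums(diff(p)^2)))

# scale a point set by factor s about a fixed center (2-vector)
scale_about <- function(p, center, s) {
  sweep(sweep(p, 2, center) * s, 2, center, FUN = "+")
}

# per-frame length scale factors with exact (max-min)/mean = amplitude
oscillation_scales <- function(n_frames, amplitude) {
  if (amplitude == 0) return(rep(1, n_frames))
  repeat {
    phi <- runif(1, 0, 2 * pi)
    r <- sin(2 * pi * (seq_len(n_frames) - 1) / n_frames + phi)
    if (max(r) - min(r) > 0.2) break
  }
  1 + amplitude * (r - mean(r)) / (max(r) - min(r))
}

# minimum distance between two point sets (coarse, decimated)
min_set_dist <- function(a, b) {
  a <- a[seq(1, nrow(a), by = 3), , drop = FALSE]
  b <- b[seq(1, nrow(b), by = 3), , drop = FALSE]
  min(sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2))
}

#' Generate a synthetic mitochondria movie with known ground truth
#'
#' Objects are smooth random curves with lengths drawn uniformly from the
#' preset's range, rasterized at the preset pixel size, dilated to the
#' tubule width, blurred by a Gaussian PSF, and corrupted by noise, then
#' quantized to 8-bit. Per frame, each object's length is scaled about its
#' midpoint by a sinusoidal oscillation (random phase per object) whose
#' (max-min)/mean over the series equals the preset's `osc_amplitude`
#' exactly; centroids perform a small random walk. If `event_rate > 0`,
#' objects may undergo fission (a permanent split; the larger fragment
#' keeps the identity). The ground-truth table records every frame's true
#' subpixel lengths and centroids. Output is bit-reproducible for a fixed
#' `(preset, n_frames, seed)`.
#'
#' @param preset a [mito_preset()] or its name.
#' @param n_frames number of frames (>= 2; default 8).
#' @param seed integer RNG seed (required).
#' @return list with `movie` (a [movie()]) and `truth` (tibble `frame`,
#'   `object`, `true_length_um`, `centroid_y`, `centroid_x`, `scale`), with
#'   attributes `preset`, `seed`.
#' @export
generate_mito_movie <- function(preset = "control_mito", n_frames = 8, seed) {
  if (is.character(preset)) preset <- mito_preset(preset)
  stopifnot(inherits(preset, "mito_preset"), n_frames >= 2)
  if (missing(seed)) stop("seed is required for reproducibility")
  set.seed(seed)
  p <- preset
  px <- p$pixel_size_um
  fld <- p$field_px
  width_px <- max(1, round(p$tubule_width_um / px))
  psf_px <- p$psf_sigma_um / px
  s_max <- 1 + p$osc_amplitude  # conservative bound on the largest scale
  margin <- ceiling(width_px + 3 * psf_px + 4)
  min_sep <- width_px + 2 * psf_px + 4

  # place base curves without overlap (checked at maximal oscillation scale)
  curves <- list()
  for (i in seq_len(p$n_objects)) {
    placed <- FALSE
    for (try in seq_len(300)) {
      L_um <- runif(1, p$length_range_um[1], p$length_range_um[2])
      crv_max <- random_curve(L_um / px * s_max, fld, margin)
      if (is.null(crv_max)) next
      ctr <- colMeans(crv_max)
      ok <- TRUE
      for (other in curves) {
        o_max <- scale_about(other$base, colMeans(other$base), s_max)
        if (min_set_dist(crv_max, o_max) < min_sep) { ok <- FALSE; break }
      }
      if (!ok) next
      # curve was generated at its maximal scale; store the base (scale 1)
      curves[[i]] <- list(base = scale_about(crv_max, ctr, 1 / s_max), id = i)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place object ", i, " without overlap after 300 tries; ",
           "reduce n_objects or lengths, or enlarge field_px")
  }

  # fission events: permanent splits; larger fragment keeps the identity
  next_id <- p$n_objects + 1L
  objects <- lapply(curves, function(cv)
    list(base = cv$base, id = cv$id, birth = 1L))
  if (p$event_rate > 0) {
    for (f in 2:n_frames) {
      for (k in seq_along(objects)) {
        ob <- objects[[k]]
        if (ob$birth > f || nrow(ob$base) < 12L) next
        if (runif(1) < p$event_rate) {
          cut <- round(nrow(ob$base) * runif(1, 1 / 3, 2 / 3))
          a <- ob$base[1:cut, , drop = FALSE]
          b <- ob$base[(cut + 1):nrow(ob$base), , drop = FALSE]
          big <- if (nrow(a) >= nrow(b)) a else b
          small <- if (nrow(a) >= nrow(b)) b else a
          objects[[k]] <- list(base = big, id = ob$id, birth = ob$birth,
                               split_at = f)
          objects[[length(objects) + 1L]] <-
            list(base = small, id = next_id, birth = f)
          next_id <- next_id + 1L
        }
      }
    }
  }

  scales <- lapply(objects, function(o) oscillation_scales(n_frames,
                                                           p$osc_amplitude))
  jit_px <- p$jitter_um / px
  jitters <- lapply(objects, function(o) {
    dy <- cumsum(c(0, rnorm(n_frames - 1, 0, jit_px)))
    dx <- cumsum(c(0, rnorm(n_frames - 1, 0, jit_px)))
    cbind(dy, dx)
  })

  brush_sz <- 2L * (width_px %/% 2L) + 1L
  brush <- if (brush_sz >= 3L) EBImage::makeBrush(brush_sz, "disc") else NULL
  frames <- vector("list", n_frames)
  truth <- list()
  for (f in seq_len(n_frames)) {
    canvas <- matrix(0, fld, fld)
    for (k in seq_along(objects)) {
      ob <- objects[[k]]
      if (ob$birth > f) next
      s <- scales[[k]][f]
      pts <- scale_about(ob$base, colMeans(ob$base), s)
      pts <- sweep(pts, 2, jitters[[k]][f, ], FUN = "+")
      ij <- unique(round(pts))
      ij <- ij[ij[, 1] >= 1 & ij[, 1] <= fld & ij[, 2] >= 1 & ij[, 2] <= fld,
               , drop = FALSE]
      canvas[ij] <- 1
      truth[[length(truth) + 1L]] <- tibble(
        frame = f, object = ob$id,
        true_length_um = polyline_length(pts) * px,
        centroid_y = mean(pts[, 1]), centroid_x = mean(pts[, 2]),
        scale = s)
    }
    if (!is.null(brush)) canvas <- EBImage::dilate(canvas, brush)
    canvas <- EBImage::gblur(canvas, sigma = psf_px)
    img <- p$background + p$peak_intensity * canvas
    if (isTRUE(p$poisson_noise)) img <- matrix(rpois(length(img), img),
                                               fld, fld)
    if (p$noise_sigma > 0) img <- img + rnorm(length(img), 0, p$noise_sigma)
    frames[[f]] <- round(pmin(pmax(img, 0), 255))
  }
  truth <- dplyr::arrange(dplyr::bind_rows(truth), .data$frame, .data$object)
  out <- list(movie = movie(frames, pixel_size_um = px,
                            time_step_s = p$time_step_s),
              truth = truth)
  attr(out, "preset") <- p$name
  attr(out, "seed") <- seed
  out
}

#' Shipped FRAP simulation presets
#'
#' `"control_frap"` encodes efficient trafficking (mobile fraction 0.92,
#' tau 240 s: ~90% recovery 15 min after the bleach); `"mutant_frap"`
#' encodes impaired exchange (mobile fraction 0.55, tau 375 s: ~50% at
#' 15 min). Both sample every 2 min with 2% multiplicative noise.
#'
#' @param name `"control_frap"` or `"mutant_frap"`, or a list of fields.
#' @return list of class `frap_preset`.
#' @export
frap_preset <- function(name = c("control_frap", "mutant_frap")) {
  if (is.list(name)) return(structure(name, class = "frap_preset"))
  name <- match.arg(name)
  cond <- switch(name,
    control_frap = list(mobile_fraction = 0.92, tau_s = 240),
    mutant_frap = list(mobile_fraction = 0.55, tau_s = 375))
  structure(c(list(name = name, prebleach_level = 200, bleach_depth = 0.9,
                   sample_interval_s = 120, duration_s = 1800,
                   noise_sigma = 0.02, n_prebleach = 3), cond),
            class = "frap_preset")
}

#' Generate a synthetic FRAP intensity series
#'
#' Prebleach samples sit at `prebleach_level`; the bleach drops intensity to
#' `F0 = prebleach_level * (1 - bleach_depth)`; recovery follows
#' `F(t) = F0 + (F_inf - F0) * (1 - exp(-t/tau))` with `F_inf` chosen so the
#' true asymptotic recovery fraction equals `mobile_fraction`. Multiplicative
#' Gaussian noise (`* (1 + N(0, noise_sigma))`) is applied to every sample.
#'
#' @param mobile_fraction true mobile fraction in `[0, 1]`.
#' @param tau_s recovery time constant (s, > 0).
#' @param prebleach_level,bleach_depth,sample_interval_s,duration_s,noise_sigma,n_prebleach
#'   acquisition parameters; defaults match the shipped presets.
#' @param seed integer RNG seed (required).
#' @return list with `curve` (tibble `time_s`, `intensity`) and `truth`
#'   (list: `mobile_fraction`, `tau_s`, `F_pre`, `F0`, `F_inf`,
#'   `bleach_index`).
#' @export
generate_frap_series <- function(mobile_fraction, tau_s,
                                 prebleach_level = 200, bleach_depth = 0.9,
                                 sample_interval_s = 120, duration_s = 1800,
                                 noise_sigma = 0.02, n_prebleach = 3, seed) {
  if (mobile_fraction < 0 || mobile_fraction > 1)
    stop("mobile_fraction must be in [0, 1]")
  if (tau_s <= 0) stop("tau_s must be positive")
  if (bleach_depth <= 0 || bleach_depth > 1)
    stop("bleach_depth must be in (0, 1]")
  if (missing(seed)) stop("seed is required for reproducibility")
  set.seed(seed)
  times <- seq(0, duration_s, by = sample_interval_s)
  if (length(times) < n_prebleach + 4L)
    stop("duration too short for ", n_prebleach, " prebleach + 4 post-bleach samples")
  f0 <- prebleach_level * (1 - bleach_depth)
  f_inf <- f0 + mobile_fraction * (prebleach_level - f0)
  bleach_index <- n_prebleach + 1L
  t0 <- times[bleach_index]
  intensity <- ifelse(times < t0, prebleach_level,
                      f0 + (f_inf - f0) * (1 - exp(-(times - t0) / tau_s)))
  if (noise_sigma > 0)
    intensity <- intensity * (1 + rnorm(length(intensity), 0, noise_sigma))
  list(curve = tibble(time_s = times, intensity = pmax(intensity, 0)),
       truth = list(mobile_fraction = mobile_fraction, tau_s = tau_s,
                    F_pre = prebleach_level, F0 = f0, F_inf = f_inf,
                    bleach_index = bleach_index))
}

#' Generate a field of cells containing bright puncta, with known counts
#'
#' Cells are disjoint disks on a grid; each cell receives a puncta count
#' drawn from `count_distribution` and that many Gaussian spots, placed
#' uniformly inside the cell with a minimum separation of 4 sigma. Spots are
#' rendered over a flat background with additive Gaussian noise and
#' quantized to 8-bit.
#'
#' @param n_cells number of cells (>= 1).
#' @param count_distribution either a function `n -> integer vector` (e.g.
#'   `function(n) rpois(n, 10)`), or a single non-negative integer used for
#'   every cell.
#' @param spot_sigma_px Gaussian sigma of each spot (default 1.5).
#' @param spot_amplitude peak height above background (default 150).
#' @param background flat background level (default 20).
#' @param noise_sigma additive Gaussian noise SD (default 2).
#' @param cell_radius_px disk radius of each cell (default 24, large enough
#'   to hold ~20 well-separated spots).
#' @param seed integer RNG seed (required).
#' @return list with `image` (matrix), `cell_labels` (integer matrix) and
#'   `truth` (tibble `cell`, `true_count`, `center_y`, `center_x`).
#' @export
generate_puncta_field <- function(n_cells, count_distribution,
                                  spot_sigma_px = 1.5, spot_amplitude = 150,
                                  background = 20, noise_sigma = 2,
                                  cell_radius_px = 24, seed) {
  stopifnot(n_cells >= 1)
  if (missing(seed)) stop("seed is required for reproducibility")
  set.seed(seed)
  counts <- if (is.function(count_distribution)) {
    as.integer(count_distribution(n_cells))
  } else {
    rep(as.integer(count_distribution), n_cells)
  }
  stopifnot(length(counts) == n_cells, all(counts >= 0))
  pitch <- 2L * cell_radius_px + 8L
  ncol_g <- ceiling(sqrt(n_cells))
  nrow_g <- ceiling(n_cells / ncol_g)
  ny <- nrow_g * pitch; nx <- ncol_g * pitch
  labels <- matrix(0L, ny, nx)
  img <- matrix(background, ny, nx)
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  centers <- matrix(0, n_cells, 2)
  min_sep <- 4 * spot_sigma_px
  place_r <- cell_radius_px - max(3 * spot_sigma_px, 2)
  if (place_r <= 0) stop("cell_radius_px too small for the spot size")
  hw <- ceiling(4 * spot_sigma_px)
  for (c_i in seq_len(n_cells)) {
    gy <- (c_i - 1) %/% ncol_g; gx <- (c_i - 1) %% ncol_g
    cy <- gy * pitch + pitch / 2; cx <- gx * pitch + pitch / 2
    centers[c_i, ] <- c(cy, cx)
    inside <- (yy - cy)^2 + (xx - cx)^2 <= cell_radius_px^2
    labels[inside] <- c_i
    if (counts[c_i] == 0L) next
    # sequential dart-throwing with whole-cell restarts: a single unlucky
    # sequence should not abort a feasible packing
    pts <- NULL
    for (restart in seq_len(30)) {
      pts <- matrix(NA_real_, counts[c_i], 2)
      filled <- TRUE
      for (s_i in seq_len(counts[c_i])) {
        ok <- FALSE
        for (try in seq_len(200)) {
          ang <- runif(1, 0, 2 * pi); rad <- place_r * sqrt(runif(1))
          cand <- c(cy + rad * sin(ang), cx + rad * cos(ang))
          if (s_i == 1L ||
              all(rowSums(sweep(pts[seq_len(s_i - 1), , drop = FALSE], 2,
                                cand)^2) >= min_sep^2)) {
            pts[s_i, ] <- cand; ok <- TRUE; break
          }
        }
        if (!ok) { filled <- FALSE; break }
      }
      if (filled) break
      pts <- NULL
    }
    if (is.null(pts))
      stop("could not fit ", counts[c_i], " spots in cell ", c_i,
           "; enlarge cell_radius_px or reduce counts")
    for (s_i in seq_len(counts[c_i])) {
      py <- pts[s_i, 1]; px_ <- pts[s_i, 2]
      ys <- max(1, floor(py) - hw):min(ny, ceiling(py) + hw)
      xs <- max(1, floor(px_) - hw):min(nx, ceiling(px_) + hw)
      d2 <- outer((ys - py)^2, (xs - px_)^2, "+")
      img[ys, xs] <- img[ys, xs] +
        spot_amplitude * exp(-d2 / (2 * spot_sigma_px^2))
    }
  }
  if (noise_sigma > 0) img <- img + rnorm(length(img), 0, noise_sigma)
  img <- round(pmin(pmax(img, 0), 255))
  list(image = img, cell_labels = labels,
       truth = tibble(cell = seq_len(n_cells), true_count = counts,
                      center_y = centers[, 1], center_x = centers[, 2]))
}
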