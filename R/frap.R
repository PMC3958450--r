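#' ROI mean-intensity time series from a movie
#'
#' @param x a [movie()].
#' @param r a [roi()].
#' @return tibble with `time_s` (from the movie's time step, first frame at
#'   0) and `intensity` (mean over the ROI).
#' @export
extract_roi_series <- function(x, r) {
  stopifnot(inherits(x, "mito_movie"))
  roi_check(r, dim(x$frames[[1]]))
  rows <- r$y0:(r$y0 + r$height - 1L)
  cols <- r$x0:(r$x0 + r$width - 1L)
  tibble(
    time_s = (seq_along(x$frames) - 1) * x$time_step_s,
    intensity = vapply(x$frames, function(f) mean(f[rows, cols]), numeric(1))
  )
}

check_curve <- function(curve) {
  stopifnot(is.data.frame(curve),
            all(c("time_s", "intensity") %in% names(curve)))
  if (is.unsorted(curve$time_s, strictly = TRUE))
    stop("times must be strictly increasing")
  invisible(curve)
}

#' Locate the photobleach in an intensity series
#'
#' Finds the largest single-step intensity drop and accepts it as the bleach
#' if it exceeds half of the running mean of the samples before it (the
#' prebleach level up to that point). The returned index is the first
#' post-bleach sample.
#'
#' @param curve tibble with `time_s`, `intensity` (>= 3 samples).
#' @return integer index of the first post-bleach sample.
#' @export
detect_bleach <- function(curve) {
  check_curve(curve)
  x <- curve$intensity
  if (length(x) < 3L) stop("need at least 3 samples")
  drops <- -diff(x)  # drops[i] = x[i] - x[i+1]
  i <- which.max(drops)
  pre_mean <- mean(x[seq_len(i)])
  if (drops[i] <= 0.5 * pre_mean)
    stop("no qualifying bleach: largest drop does not exceed 50% of the prebleach mean")
  i + 1L
}

#' Percent fluorescence recovery at a time after bleaching
#'
#' Normalizes the curve as `100 * (F(t) - F0) / (F_pre - F0)`, where `F_pre`
#' is the mean of all prebleach samples and `F0` the intensity at the bleach
#' index, and evaluates it at `t_s` seconds after the bleach by linear
#' interpolation between the bracketing samples. The normalization is
#' invariant under affine rescaling of the whole curve.
#'
#' @param curve tibble with `time_s`, `intensity`.
#' @param t_s evaluation time in seconds after the bleach.
#' @param bleach index of the first post-bleach sample; located with
#'   [detect_bleach()] by default.
#' @return percent recovery.
#' @export
recovery_percent <- function(curve, t_s, bleach = detect_bleach(curve)) {
  check_curve(curve)
  x <- curve$intensity
  f_pre <- mean(x[seq_len(bleach - 1L)])
  f0 <- x[bleach]
  if (f_pre <= f0) stop("prebleach mean must exceed the bleach-floor intensity")
  tt <- curve$time_s - curve$time_s[bleach]
  if (t_s < 0 || t_s > max(tt)) stop("t_s outside the post-bleach span of the curve")
  ft <- approx(tt, x, xout = t_s)$y
  100 * (ft - f0) / (f_pre - f0)
}

#' Fit an exponential recovery model to a FRAP curve
#'
#' Fits `F(t) = F0 + (F_inf - F0) * (1 - exp(-(t - t0)/tau))` to the
#' post-bleach samples by least squares, with `F0` fixed at the intensity of
#' the bleach-index sample and `t0` at its time (fixing the floor avoids the
#' degeneracy between a deep fast recovery and a shallow slow one). The
#' mobile fraction is `(F_inf - F0) / (F_pre - F0)`, reported clipped to
#' `[0, 1]` with the raw value retained. Initialization is deterministic:
#' `F_inf` starts at the last sample, `tau` at half the post-bleach span.
#'
#' @param curve tibble with `time_s`, `intensity` (>= 4 post-bleach samples).
#' @param bleach index of the first post-bleach sample.
#' @return object of class `frap_fit` with fields `F_pre`, `F0`, `F_inf`,
#'   `tau_s`, `mobile_fraction`, `mobile_fraction_raw`, `rss`, `n_post`,
#'   `bleach_index`, `curve`. Supports `tidy()`, `glance()`, `autoplot()`.
#' @export
fit_recovery <- function(curve, bleach = detect_bleach(curve)) {
  check_curve(curve)
  x <- curve$intensity
  n <- length(x)
  if (n - bleach + 1L < 4L) stop("need at least 4 post-bleach samples")
  f_pre <- mean(x[seq_len(bleach - 1L)])
  f0 <- x[bleach]
  if (f_pre - f0 <= 1e-9 * max(abs(f_pre), 1))
    stop("degenerate curve: prebleach level does not exceed the bleach floor")
  post <- bleach:n
  tt <- curve$time_s[post] - curve$time_s[bleach]
  yy <- x[post]
  if (sd(yy) == 0) {
    # exactly flat post-bleach series: no recovery, tau unidentifiable
    mf_raw <- (yy[1] - f0) / (f_pre - f0)
    return(structure(
      list(F_pre = f_pre, F0 = f0, F_inf = yy[1], tau_s = NA_real_,
           mobile_fraction = min(max(mf_raw, 0), 1),
           mobile_fraction_raw = mf_raw,
           rss = 0, n_post = length(post),
           bleach_index = bleach, curve = curve),
      class = "frap_fit"))
  }
  dat <- data.frame(t = tt, y = yy)
  # a barely-recovering series makes Finf - F0 ~ 0 and the tau gradient
  # vanish; nudge the Finf start off the floor so the model matrix is full
  # rank at the initial estimates. The tau start walks a deterministic
  # ladder because the initial-QR rank check is occasionally (and
  # harmlessly) tripped by an unlucky start.
  finf0 <- max(yy[length(yy)], f0 + 0.05 * (f_pre - f0))
  fit <- NULL
  for (tau0 in max(tt) / c(2, 4, 8, 1)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ f0 + (Finf - f0) * (1 - exp(-t / tau)),
        data = dat,
        start = list(Finf = finf0, tau = tau0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop("recovery fit did not converge")
  cf <- coef(fit)
  mf_raw <- (cf[["Finf"]] - f0) / (f_pre - f0)
  structure(
    list(F_pre = f_pre, F0 = f0, F_inf = cf[["Finf"]], tau_s = cf[["tau"]],
         mobile_fraction = min(max(mf_raw, 0), 1),
         mobile_fraction_raw = mf_raw,
         rss = sum(resid(fit)^2), n_post = length(post),
         bleach_index = bleach, curve = curve),
    class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    "<frap_fit> mobile fraction %.3f, tau %.1f s (F_pre %.1f, F0 %.1f, F_inf %.1f)\n",
    x$mobile_fraction, x$tau_s, x$F_pre, x$F0, x$F_inf))
  invisible(x)
}

#' Parameter table of a FRAP fit
#' @param x a `frap_fit`.
#' @param ... unused.
#' @return tibble with one row per parameter.
#' @export
tidy.frap_fit <- function(x, ...) {
  tibble(term = c("F_pre", "F0", "F_inf", "tau_s", "mobile_fraction"),
         estimate = c(x$F_pre, x$F0, x$F_inf, x$tau_s, x$mobile_fraction))
}

#' One-row summary of a FRAP fit
#' @param x a `frap_fit`.
#' @param ... unused.
#' @return one-row tibble.
#' @export
glance.frap_fit <- function(x, ...) {
  tibble(mobile_fraction = x$mobile_fraction,
         mobile_fraction_raw = x$mobile_fraction_raw,
         tau_s = x$tau_s, F_pre = x$F_pre, F0 = x$F0, F_inf = x$F_inf,
         rss = x$rss, n_post = x$n_post)
}

#' Has the recovery plateaued?
#'
#' `TRUE` iff the last two samples differ by less than
#' `epsilon_frac * F_pre`, i.e. fluorescence no longer changes between
#' consecutive scans.
#'
#' @param curve tibble with `time_s`, `intensity` (>= 2 samples).
#' @param epsilon_frac tolerance as a fraction of the prebleach mean.
#' @param bleach index of the first post-bleach sample (for `F_pre`).
#' @return logical.
#' @export
plateau_reached <- function(curve, epsilon_frac = 0.02,
                            bleach = detect_bleach(curve)) {
  check_curve(curve)
  x <- curve$intensity
  if (length(x) < 2L) stop("need at least 2 samples")
  f_pre <- mean(x[seq_len(bleach - 1L)])
  abs(x[length(x)] - x[length(x) - 1L]) < epsilon_frac * f_pre
}
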