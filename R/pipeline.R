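#' Run the morphology-dynamics pipeline end-to-end
#'
#' Chains segmentation, tracking and dynamics summarisation on one movie.
#' The movie comes either from a synthetic preset (`config$input$preset`,
#' with `config$seed`) or from a TIFF stack (`config$input$path` with
#' calibration). All stage parameters are optional config keys with the
#' package defaults. When `config$out_dir` is set, the per-object table
#' (`objects.csv`), the tracked table (`tracks.csv`) and the condition
#' summary (`summary.json`) are written there.
#'
#' @param config a named list (see Details) or the path to a YAML file for
#'   [read_run_config()].
#' @return list with `summary` (a `dynamics_summary`), `tracks`, `objects`
#'   (tibbles) and `movie`.
#' @details Config keys: `input` (`preset` + `n_frames`, or `path` +
#'   `pixel_size_um` + `time_step_s`, optionally `roi` and `z_plane`),
#'   `seed`, `segmentation` (`mode`, `radius`, `offset`, `min_contrast`,
#'   `min_area_px`, `tubule_sigma_px`, `response_threshold`,
#'   `cap_correction`), `tracking`
#'   (`max_disp_px`, `memory_frames`), `dynamics` (`min_track_len`),
#'   `out_dir`.
#' @export
run_mito <- function(config) {
  cfg <- load_config(config)
  mv <- config_movie(cfg)
  sg <- cfg$segmentation %||% list()
  mode <- sg$mode %||% "midgrey"
  objects <- with_stage("segmentation", segment_movie(
    mv, mode = mode,
    radius = sg$radius %||% 15, offset = sg$offset %||% 0,
    min_contrast = sg$min_contrast %||% 25,
    min_area_px = sg$min_area_px %||% 9,
    tubule_sigma_px = sg$tubule_sigma_px %||% 2,
    response_threshold = sg$response_threshold %||% 0.04,
    cap_correction = sg$cap_correction %||% TRUE))
  if (nrow(objects) == 0L) stop("segmentation: no objects segmented")
  tk <- cfg$tracking %||% list()
  tracks <- with_stage("tracking", link_tracks(
    objects, max_disp_px = tk$max_disp_px %||% 20,
    memory_frames = tk$memory_frames %||% 2))
  dy <- cfg$dynamics %||% list()
  summary <- with_stage("dynamics", summarize_dynamics(
    tracks, pixel_size_um = mv$pixel_size_um,
    min_track_len = dy$min_track_len %||% 3))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(dplyr::select(objects, -"path"),
              file.path(cfg$out_dir, "objects.csv"), row.names = FALSE)
    write.csv(dplyr::select(tracks, -"path"),
              file.path(cfg$out_dir, "tracks.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(condition = summary$condition, tracks = summary$tracks),
      file.path(cfg$out_dir, "summary.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  list(summary = summary, tracks = tracks, objects = objects, movie = mv)
}

#' Run the FRAP pipeline on a batch of series
#'
#' Each series comes from a synthetic FRAP preset (`config$input$preset`,
#' replicated `config$input$n_series` times with seeds `seed, seed+1, ...`)
#' or from two-column CSV files (`config$input$paths`, columns `time_s`,
#' `intensity`). For every series the bleach is located, recovery percent is
#' evaluated at `config$t_eval_s` (default 900 s) and the exponential model
#' is fitted.
#'
#' @param config named list or YAML path.
#' @return tibble with one row per series: `series`, `bleach_index`,
#'   `recovery_pct`, `mobile_fraction`, `tau_s`, `plateau`.
#' @export
run_frap <- function(config) {
  cfg <- load_config(config)
  t_eval <- cfg$t_eval_s %||% 900
  curves <- if (!is.null(cfg$input$preset)) {
    pr <- frap_preset(cfg$input$preset)
    n <- cfg$input$n_series %||% 1L
    seed <- cfg$seed %||% stop("seed required for synthetic FRAP runs")
    lapply(seq_len(n), function(i)
      generate_frap_series(
        mobile_fraction = pr$mobile_fraction, tau_s = pr$tau_s,
        prebleach_level = pr$prebleach_level, bleach_depth = pr$bleach_depth,
        sample_interval_s = pr$sample_interval_s, duration_s = pr$duration_s,
        noise_sigma = pr$noise_sigma, n_prebleach = pr$n_prebleach,
        seed = seed + i - 1L)$curve)
  } else {
    lapply(cfg$input$paths, function(p) {
      d <- read.csv(p)
      tibble(time_s = d$time_s, intensity = d$intensity)
    })
  }
  out <- purrr::map_dfr(seq_along(curves), function(i) {
    cv <- curves[[i]]
    with_stage(paste0("frap[series ", i, "]"), {
      b <- detect_bleach(cv)
      fit <- fit_recovery(cv, bleach = b)
      tibble(series = i, bleach_index = b,
             recovery_pct = recovery_percent(cv, t_eval, bleach = b),
             mobile_fraction = fit$mobile_fraction, tau_s = fit$tau_s,
             plateau = plateau_reached(cv, bleach = b))
    })
  })
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(out, file.path(cfg$out_dir, "frap_fits.csv"), row.names = FALSE)
  }
  out
}

#' Run the puncta pipeline on one or more conditions
#'
#' Each condition is a synthetic puncta field (`n_cells`, and `lambda` for
#' Poisson counts or `count` for a fixed count) or a TIFF pair (`path`,
#' `labels_path`). Per condition the spots are detected, counted per cell,
#' scored against the >5 positivity rule and averaged into the autophagy
#' index. With exactly two conditions, the fold change of the second over
#' the first condition's index is reported.
#'
#' @param config named list or YAML path; `config$conditions` is a named or
#'   unnamed list of condition specs.
#' @return list with `summary` (tibble: one row per condition), `cells`
#'   (tibble of per-cell counts), and `fold_change` (second index over
#'   first; `NA` unless there are exactly two conditions).
#' @export
run_puncta <- function(config) {
  cfg <- load_config(config)
  conds <- cfg$conditions
  if (is.null(conds)) stop("config must have a 'conditions' list")
  nm <- names(conds) %||% paste0("condition_", seq_along(conds))
  nm[nm == ""] <- paste0("condition_", which(nm == ""))
  seed <- cfg$seed %||% 7L
  det <- cfg$detection %||% list()
  res <- purrr::map(seq_along(conds), function(i) {
    cc <- conds[[i]]
    with_stage(paste0("puncta[", nm[i], "]"), {
      if (!is.null(cc$path)) {
        img <- read_stack(cc$path, pixel_size_um = 1, time_step_s = 1)$frames[[1]]
        lab <- read_stack(cc$labels_path, pixel_size_um = 1,
                          time_step_s = 1)$frames[[1]]
        storage.mode(lab) <- "integer"
      } else {
        dist <- if (!is.null(cc$lambda)) {
          lam <- cc$lambda
          function(n) rpois(n, lam)
        } else {
          cc$count %||% stop("condition needs 'lambda', 'count' or 'path'")
        }
        fld <- generate_puncta_field(
          n_cells = cc$n_cells %||% 200, count_distribution = dist,
          seed = seed + i - 1L)
        img <- fld$image; lab <- fld$cell_labels
      }
      analyze_puncta(img, lab,
                     sigma_min_px = det$sigma_min_px %||% 1,
                     sigma_max_px = det$sigma_max_px %||% 3,
                     k_background = det$k_background %||% 3)
    })
  })
  summary <- purrr::map_dfr(seq_along(res), function(i)
    dplyr::bind_cols(tibble(condition = nm[i]), glance(res[[i]])))
  cells <- purrr::map_dfr(seq_along(res), function(i)
    dplyr::bind_cols(tibble(condition = nm[i]), res[[i]]$cells))
  fc <- if (length(res) == 2L) {
    fold_change(res[[2]]$autophagy_index, res[[1]]$autophagy_index)
  } else NA_real_
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(cells, file.path(cfg$out_dir, "puncta_cells.csv"),
              row.names = FALSE)
    jsonlite::write_json(list(summary = summary, fold_change = fc),
                         file.path(cfg$out_dir, "puncta_summary.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  list(summary = summary, cells = cells, fold_change = fc)
}

load_config <- function(config) {
  if (is.character(config)) read_run_config(config) else config
}

config_movie <- function(cfg) {
  if (!is.null(cfg$input$preset)) {
    seed <- cfg$seed %||% stop("seed required for synthetic runs")
    generate_mito_movie(cfg$input$preset,
                        n_frames = cfg$input$n_frames %||% 8,
                        seed = seed)$movie
  } else {
    mv <- read_stack(cfg$input$path,
                     pixel_size_um = cfg$input$pixel_size_um,
                     time_step_s = cfg$input$time_step_s)
    if (!is.null(cfg$input$roi)) {
      r <- cfg$input$roi
      mv <- crop_movie(mv, roi(r$x0, r$y0, r$width, r$height))
    }
    mv
  }
}

# wrap a stage so errors carry the stage name and context
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(stage, ": ", conditionMessage(e), call. = FALSE)
  })
}
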