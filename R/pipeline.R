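# Batch orchestration: video -> detections -> tracks -> kinematics ->
# persistence + collective statistics -> CSV report bundle. Every bundle
# embeds the complete parameter set and seed, so two runs with equal embedded
# configs are byte-identical.

#' Analyze a track table into a full report bundle
#'
#' Computes kinematics at the configured interval size, the population
#' summary, the population persistence fit, and the three-mode PRMI, and
#' writes `percell.csv`, `population.csv`, `persistence.csv`, `prmi.csv` and
#' `run_log.yaml` to `out_dir`.
#'
#' @param tracks Track tibble (`cell_id`, `frame`, `x`, `y`).
#' @param out_dir Output directory.
#' @param config An [acquisition()] object.
#' @param seed Integer seed for the PRMI random modes.
#' @param radius_um Neighbor radius for the PRMI, micrometers.
#' @param fit_window Lag window for [fit_persistence()], minutes.
#' @param prefix Filename prefix for the bundle.
#' @param extra_log Named list merged into the run log (e.g. detection and
#'   linking parameters when called from [run_batch()]).
#' @return Named character vector of files written, invisibly.
#' @export
analyze_tracks <- function(tracks, out_dir, config = acquisition(), seed = 1,
                           radius_um = 100, fit_window = c(0, 240),
                           prefix = "", extra_log = list()) {
  tracks <- validate_tracks(tracks)
  kin <- compute_kinematics(tracks, config)
  summary <- summarize_population(kin)
  paths <- write_report(kin, summary, out_dir, prefix)

  fit <- tryCatch(fit_persistence(msd_curve(tracks, config), fit_window),
                  error = function(e) NULL)
  pers <- if (is.null(fit)) {
    tibble::tibble(S_um_per_min = NA_real_, P_min = NA_real_, n_d = 2,
                   rss = NA_real_, n_lags_used = 0L, converged = FALSE)
  } else {
    glance(fit)
  }
  pers_path <- file.path(out_dir, paste0(prefix, "persistence.csv"))
  readr::write_csv(pers, pers_path, progress = FALSE)

  prmi_tbl <- suppressWarnings(dplyr::bind_rows(
    prmi(kin, "nearest_neighbor", config, radius_um),
    prmi(kin, "random_pairing", config, radius_um, seed = seed),
    prmi(kin, "random_angles", config, radius_um, seed = seed)
  ))
  prmi_path <- file.path(out_dir, paste0(prefix, "prmi.csv"))
  readr::write_csv(prmi_tbl, prmi_path, progress = FALSE)

  log_path <- file.path(out_dir, paste0(prefix, "run_log.yaml"))
  yaml::write_yaml(c(list(
    acquisition = unclass(config), seed = seed, radius_um = radius_um,
    fit_window = fit_window, n_tracks = length(unique(tracks$cell_id))
  ), extra_log), log_path)

  invisible(c(paths, persistence = pers_path, prmi = prmi_path,
              run_log = log_path))
}

#' Run the statistics bundle on a pre-computed track CSV
#'
#' @param track_csv Path to a CSV with columns `cell_id`, `frame`, `x`, `y`.
#' @param out_dir Output directory.
#' @inheritParams analyze_tracks
#' @return Files written, invisibly.
#' @export
run_tracks_only <- function(track_csv, out_dir, config = acquisition(),
                            seed = 1, radius_um = 100,
                            fit_window = c(0, 240)) {
  analyze_tracks(read_tracks_csv(track_csv), out_dir, config, seed,
                 radius_um, fit_window,
                 extra_log = list(input = basename(track_csv)))
}

#' Run the full pipeline over a folder of videos
#'
#' Processes every `.tif`/`.tiff`/`.avi` in `input_dir` independently:
#' detection, linking, kinematics, persistence and PRMI, one report bundle
#' per video (files prefixed with the video name). Unreadable videos are
#' logged and skipped. `n_workers` is accepted for interface compatibility;
#' results are independent of it by construction (videos are processed in
#' isolation with fixed seeds).
#'
#' @param input_dir Folder containing at least one readable video.
#' @param out_dir Output directory.
#' @param config An [acquisition()] object.
#' @param detection A [detection_params()] object.
#' @param linking A [linking_params()] object.
#' @param seed Integer seed.
#' @param radius_um PRMI neighbor radius, micrometers.
#' @param n_workers Ignored beyond validation (must be >= 1).
#' @return Tibble with one row per video: `video`, `status`, `n_tracks`.
#' @export
run_batch <- function(input_dir, out_dir, config = acquisition(),
                      detection = detection_params(),
                      linking = linking_params(), seed = 1, radius_um = 100,
                      n_workers = 1) {
  stopifnot(n_workers >= 1)
  if (!dir.exists(input_dir)) {
    stop("input folder not found: ", input_dir, call. = FALSE)
  }
  videos <- list.files(input_dir, pattern = "\\.(tif|tiff|avi)$",
                       ignore.case = TRUE, full.names = TRUE)
  if (length(videos) == 0) {
    stop("no videos (*.tif, *.tiff, *.avi) in ", input_dir, call. = FALSE)
  }
  results <- purrr::map(videos, function(v) {
    name <- tools::file_path_sans_ext(basename(v))
    res <- tryCatch({
      stack <- read_stack(v, config)
      dets <- detect_nuclei(stack, detection)
      tracks <- link_tracks(dets, linking)
      if (nrow(tracks) == 0) {
        stop("no tracks of length >= ", linking$min_track_length, call. = FALSE)
      }
      analyze_tracks(tracks, out_dir, config, seed, radius_um,
                     prefix = paste0(name, "_"),
                     extra_log = list(video = basename(v),
                                      detection = unclass(detection),
                                      linking = unclass(linking)))
      tibble::tibble(video = basename(v), status = "ok",
                     n_tracks = length(unique(tracks$cell_id)))
    }, error = function(e) {
      message("skipping ", basename(v), ": ", conditionMessage(e))
      tibble::tibble(video = basename(v), status = conditionMessage(e),
                     n_tracks = 0L)
    })
    res
  })
  dplyr::bind_rows(results)
}
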