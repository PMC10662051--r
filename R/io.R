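#' Read a track table
#'
#' Reads a comma-separated track table in the style of FIESTA exports,
#' with required columns `track_id`, `t_s`, `x_nm` (extra columns are
#' preserved).  Rows are sorted by time within each track; non-uniform
#' sampling and duplicate `(track_id, t_s)` pairs are rejected with the
#' offending track id.
#'
#' @param path File path.
#' @return A tibble of tracks (class `tug_tracks`).
#' @export
read_tracks <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("track_id", "t_s", "x_nm")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0)
    rlang::abort(paste0("missing column(s): ", paste(missing, collapse = ", ")))
  for (cl in c("t_s", "x_nm")) {
    if (nrow(df) > 0 && !is.numeric(df[[cl]]))
      rlang::abort(sprintf("column `%s` must be numeric", cl))
  }
  df <- dplyr::arrange(df, .data$track_id, .data$t_s)
  for (id in unique(df$track_id)) {
    tt <- df$t_s[df$track_id == id]
    if (anyDuplicated(tt))
      rlang::abort(sprintf("duplicate time points in track %s", id))
    if (length(tt) > 2) {
      dts <- diff(tt)
      if (max(dts) - min(dts) > 1e-6 * stats::median(dts))
        rlang::abort(sprintf("non-uniform sampling in track %s", id))
    }
  }
  structure(tibble::as_tibble(df), class = c("tug_tracks", "tbl_df", "tbl",
                                             "data.frame"))
}

#' Write a track table
#'
#' @param tracks Tibble with at least `track_id`, `t_s`, `x_nm`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  readr::write_csv(tibble::as_tibble(tracks), path, progress = FALSE)
  invisible(path)
}

#' Read a simulation configuration from YAML
#'
#' Expects sections `motors.DDB`, `motors.KIF16B` and `simulation`, each
#' holding named fields of [motor_params()] / [sim_config()]; missing
#' fields fall back to the documented defaults.
#'
#' @param path YAML file path.
#' @return List with `ddb`, `kif16b` ([motor_params()]) and `config`
#'   ([sim_config()]).
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  mk <- function(defaults_fun, overrides) {
    if (is.null(overrides)) return(defaults_fun())
    do.call(defaults_fun, overrides)
  }
  list(ddb = mk(ddb_params, y$motors$DDB),
       kif16b = mk(kif16b_params, y$motors$KIF16B),
       config = mk(sim_config, y$simulation))
}

summarise_condition <- function(tracks, segments) {
  cls <- classify_tracks(segments)
  segs <- tibble::as_tibble(segments)
  runs <- segs[segs$kind != "pause", , drop = FALSE]
  pauses <- segs[segs$kind == "pause", , drop = FALSE]
  vel_summary <- function(v) {
    if (length(v) == 0) return(list(median = NA_real_, iqr = NA_real_,
                                    n = 0L))
    list(median = stats::median(v), iqr = stats::IQR(v), n = length(v))
  }
  pf <- spatial_pause_frequency(track_pause_table(segments))
  list(
    n_tracks = length(unique(segs$track_id)),
    class_fractions = class_fractions(cls),
    velocity_runs_pos = vel_summary(
      runs$mean_velocity_nm_s[runs$kind == "run_pos"]),
    velocity_runs_neg = vel_summary(
      runs$mean_velocity_nm_s[runs$kind == "run_neg"]),
    pause_frequency = as.list(pf),
    pause_duration_quartiles = if (nrow(pauses) > 0)
      as.list(stats::quantile(pauses$duration_s, c(0.25, 0.5, 0.75)))
      else NULL)
}

#' Run the simulate--segment--classify pipeline
#'
#' Executes the full analysis: simulate cargoes (or consume user tracks
#' unchanged), segment every track, classify tracks and summarise the
#' statistics; writes `tracks.csv`, `segments.csv`, `stats.json` and a
#' run manifest with the seed and configuration hash.  Idempotent under a
#' fixed seed.
#'
#' @param config List with optional elements `simulate` (list with
#'   `n_cargoes` plus [sim_config()] overrides; omit to skip simulation),
#'   `tracks_file` (input CSV when not simulating), `anneal` (list of
#'   [anneal_config()] overrides), `ddb`/`kif16b` ([motor_params()]
#'   overrides).
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param seed Integer seed driving all stages.
#' @return List with `tracks`, `segments`, `classifications`, `stats`,
#'   `manifest` (invisibly writes the artifacts when `out_dir` is set).
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, seed = 1L) {
  ddb <- do.call(ddb_params, config$ddb %||% list())
  kif <- do.call(kif16b_params, config$kif16b %||% list())
  acfg <- do.call(anneal_config, config$anneal %||% list())

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    n_cargoes <- sim$n_cargoes %||% 100L
    sim$n_cargoes <- NULL
    scfg <- do.call(sim_config, sim)
    tracks <- simulate_cargoes(n_cargoes, scfg, ddb, kif, seed = seed)
  } else if (!is.null(config$tracks_file)) {
    tracks <- read_tracks(config$tracks_file)
  } else {
    rlang::abort("config needs either `simulate` or `tracks_file`")
  }

  segments <- segment_tracks(tracks, acfg, seed = seed + 1L)
  if (nrow(segments) == 0)
    rlang::abort("no track produced any segments", class = "tug_pipeline_error")
  classifications <- classify_tracks(segments)
  stats <- summarise_condition(tracks, segments)

  manifest <- list(
    seed = seed,
    config_hash = rlang::hash(list(config, unclass(ddb), unclass(kif),
                                   unclass(acfg))),
    n_tracks = length(unique(tracks$track_id)),
    package_version = as.character(utils::packageVersion("cargotug")))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tracks(tracks, file.path(out_dir, "tracks.csv"))
    readr::write_csv(tibble::as_tibble(segments),
                     file.path(out_dir, "segments.csv"), progress = FALSE)
    jsonlite::write_json(stats, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(tracks = tracks, segments = segments,
                 classifications = classifications, stats = stats,
                 manifest = manifest))
}
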