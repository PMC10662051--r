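#' Blueprint of a synthetic piecewise-linear track
#'
#' Describes the ground truth of a synthetic track: piecewise-constant
#' velocities changing at `change_times`, localization noise, and the
#' sampling interval.  Velocities below the run threshold (in magnitude)
#' encode intended pauses.
#'
#' @param change_times Segment start times (s), increasing, first must
#'   be 0.
#' @param velocities Segment velocities (nm/s), one per change time.
#' @param duration Total track duration (s).
#' @param noise_sd Gaussian localization noise SD (nm); 20 nm matches
#'   sub-pixel tracking of 87 nm pixels.
#' @param sample_interval Sampling interval (s).
#' @return A list of class `track_blueprint`.
#' @export
track_blueprint <- function(change_times, velocities, duration,
                            noise_sd = 20, sample_interval = 0.1) {
  stopifnot(length(change_times) == length(velocities),
            change_times[1] == 0, all(diff(change_times) > 0),
            duration > max(change_times), noise_sd >= 0,
            sample_interval > 0)
  structure(list(change_times = change_times, velocities = velocities,
                 duration = duration, noise_sd = noise_sd,
                 sample_interval = sample_interval),
            class = "track_blueprint")
}

#' Generate a synthetic track with ground truth
#'
#' Integrates the blueprint's piecewise-constant velocities into a
#' piecewise-linear position signal, samples it uniformly and adds iid
#' Gaussian localization noise.  Ground-truth segment labels are obtained
#' by applying the run/pause rules (speed below `min_run_speed` or run
#' distance below `min_run_distance` is a pause) to the *noiseless*
#' signal.
#'
#' @param blueprint A [track_blueprint()].
#' @param track_id Identifier stored in the outputs.
#' @param min_run_speed,min_run_distance Labeling thresholds (nm/s, nm).
#' @param seed Optional integer seed for the noise.
#' @return A list with `track` (tibble `track_id`, `t_s`, `x_nm`) and
#'   `truth` (tibble of true segments: `t_start`, `t_end`, `velocity`,
#'   `kind`).
#' @export
make_track <- function(blueprint, track_id = 1L, min_run_speed = 100,
                       min_run_distance = 500, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bp <- blueprint
  t <- seq(0, bp$duration, by = bp$sample_interval)
  starts <- bp$change_times
  ends <- c(starts[-1], bp$duration)
  # cumulative position at segment starts
  x_start <- cumsum(c(0, bp$velocities[-length(bp$velocities)] *
                        (ends - starts)[-length(starts)]))
  seg <- findInterval(t, starts)
  x_clean <- x_start[seg] + bp$velocities[seg] * (t - starts[seg])
  x <- x_clean + stats::rnorm(length(t), 0, bp$noise_sd)
  kind <- ifelse(abs(bp$velocities) < min_run_speed, "pause",
                 ifelse(abs(bp$velocities * (ends - starts)) <
                          min_run_distance, "pause",
                        ifelse(bp$velocities > 0, "run_pos", "run_neg")))
  list(track = tibble::tibble(track_id = track_id, t_s = t, x_nm = x),
       truth = tibble::tibble(track_id = track_id, t_start = starts,
                              t_end = ends, velocity = bp$velocities,
                              kind = kind))
}

#' Sample a track-duration distribution
#'
#' Log-normal durations matched to a requested median and IQR (moment
#' matching on the log scale), truncated below at `min_duration` by
#' redrawing.  Feeds [resample_to_durations()].
#'
#' @param median,iqr Target median and IQR (s).
#' @param n Number of durations.
#' @param min_duration Lower bound (s); defaults to two 0.1 s frames.
#' @param seed Optional integer seed.
#' @return Numeric vector of durations (s).
#' @export
make_duration_sample <- function(median, iqr, n, min_duration = 0.2,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(numeric(0))
  ln <- lnorm_from_median_iqr(median, iqr)
  out <- stats::rlnorm(n, ln["meanlog"], ln["sdlog"])
  while (any(out <= min_duration)) {
    i <- out <= min_duration
    out[i] <- stats::rlnorm(sum(i), ln["meanlog"], ln["sdlog"])
  }
  out
}
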