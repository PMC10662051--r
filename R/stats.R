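#' Weighted sample
#'
#' Values with normalised non-negative weights -- the common currency of
#' the weighted statistics layer.
#'
#' @param values Numeric values.
#' @param weights Non-negative weights (normalised internally); `NULL`
#'   gives uniform weights.
#' @return A list of class `weighted_sample` with `values` and normalised
#'   `weights`.
#' @export
weighted_sample <- function(values, weights = NULL) {
  if (length(values) == 0) rlang::abort("empty sample")
  if (is.null(weights)) weights <- rep(1, length(values))
  if (length(weights) != length(values))
    rlang::abort("weights and values must have the same length")
  if (any(weights < 0) || sum(weights) <= 0)
    rlang::abort("weights must be non-negative with positive sum")
  structure(list(values = as.numeric(values),
                 weights = weights / sum(weights)),
            class = "weighted_sample")
}

#' Weighted mean, SD and SEM
#'
#' Distance-weighted estimators used for spatial pause frequencies:
#' `mean = sum(w x)`, `sd = sqrt(sum(w (x - mean)^2) / ((N-1)/N))` and
#' `sem = sd / sqrt(N - 1)`, with `N` the number of observations.  At
#' `N = 1` the SD and SEM are returned as 0 with a warning (the formulas
#' divide by `N - 1`).
#'
#' @param x Values.
#' @param w Weights (normalised internally).
#' @return Named numeric vector `mean`, `sd`, `sem`, `n`.
#' @export
weighted_moments <- function(x, w = NULL) {
  ws <- weighted_sample(x, w)
  n <- length(ws$values)
  m <- sum(ws$weights * ws$values)
  if (n == 1) {
    rlang::warn("single observation: weighted SD/SEM undefined, returning 0")
    return(c(mean = m, sd = 0, sem = 0, n = 1))
  }
  sd <- sqrt(sum(ws$weights * (ws$values - m)^2) / ((n - 1) / n))
  c(mean = m, sd = sd, sem = sd / sqrt(n - 1), n = n)
}

#' Weighted empirical cumulative distribution function
#'
#' ECDF whose step heights are the observation weights instead of `1/N`.
#'
#' @inheritParams weighted_moments
#' @return A step function (as [stats::stepfun()]).
#' @export
weighted_ecdf <- function(x, w = NULL) {
  ws <- weighted_sample(x, w)
  o <- order(ws$values)
  v <- ws$values[o]; p <- ws$weights[o]
  agg <- rowsum(p, group = v)
  knots <- as.numeric(rownames(agg))
  stats::stepfun(knots, c(0, cumsum(agg[, 1])), right = FALSE)
}

ks_pvalue <- function(z, terms = 101) {
  # two-sided asymptotic Kolmogorov tail 2 sum (-1)^(k-1) exp(-2 k^2 z^2)
  if (z <= 0) return(1)
  k <- seq_len(terms)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * z^2))
  min(1, max(0, p))
}

#' Weighted two-sample Kolmogorov--Smirnov test
#'
#' Two-sided two-sample KS test built on weighted ECDFs: the statistic is
#' the supremum over the pooled values of the difference of the two
#' weighted ECDFs.  The p-value uses the classical asymptotic formula with
#' effective sample sizes `(sum w)^2 / sum(w^2)` replacing the counts;
#' with uniform weights it reduces exactly to the unweighted asymptotic
#' two-sample test.
#'
#' @param x,y Samples.
#' @param wx,wy Optional weights (uniform if `NULL`).
#' @return A list of class `tug_ks` (and `htest`) with `statistic`,
#'   `p.value`, effective sizes, and method.
#' @export
weighted_ks_test <- function(x, y, wx = NULL, wy = NULL) {
  a <- weighted_sample(x, wx)
  b <- weighted_sample(y, wy)
  Fa <- weighted_ecdf(a$values, a$weights)
  Fb <- weighted_ecdf(b$values, b$weights)
  pooled <- sort(unique(c(a$values, b$values)))
  D <- max(abs(Fa(pooled) - Fb(pooled)))
  n_eff <- function(s, w) {
    w0 <- if (is.null(w)) rep(1, length(s)) else w
    sum(w0)^2 / sum(w0^2)
  }
  n1 <- n_eff(x, wx); n2 <- n_eff(y, wy)
  en <- sqrt(n1 * n2 / (n1 + n2))
  structure(list(statistic = c(D = D), p.value = ks_pvalue(en * D),
                 n_eff = c(n1 = n1, n2 = n2),
                 method = "Weighted two-sample Kolmogorov-Smirnov test",
                 alternative = "two-sided",
                 data.name = paste(deparse1(substitute(x)), "and",
                                   deparse1(substitute(y)))),
            class = c("tug_ks", "htest"))
}

#' Bonferroni correction
#'
#' Multiplies p-values by the number of comparisons, capped at 1.
#'
#' @param p P-values.
#' @param m_comparisons Number of comparisons.
#' @return Corrected p-values.
#' @export
bonferroni <- function(p, m_comparisons) {
  stopifnot(m_comparisons >= 1)
  pmin(1, p * m_comparisons)
}

#' Frame-to-frame instantaneous velocities
#'
#' @param track Tibble with `t_s` and `x_nm`, uniformly sampled.
#' @return Numeric vector of length `N - 1` (nm/s).
#' @export
instantaneous_velocities <- function(track) {
  if (nrow(track) < 2) rlang::abort("track needs at least 2 samples")
  diff(track$x_nm) / diff(track$t_s)
}

#' Mean velocity of a run segment
#'
#' Arithmetic mean of the instantaneous velocities inside the segment's
#' index range.
#'
#' @param track Tibble with `t_s` and `x_nm`.
#' @param segment One row of a segment table (uses `i_start`, `i_end`).
#' @return Mean velocity (nm/s).
#' @export
run_mean_velocity <- function(track, segment) {
  i0 <- segment$i_start; i1 <- segment$i_end
  if (i1 <= i0) rlang::abort("segment must span at least two samples")
  mean(diff(track$x_nm[i0:i1]) / diff(track$t_s[i0:i1]))
}

#' Distance-weighted spatial pause frequency
#'
#' Per-track pause frequency `x_f = n_pauses / distance` (1/um), averaged
#' with weights proportional to each track's distance travelled, with the
#' weighted SD and SEM of [weighted_moments()].  Tracks with zero distance
#' are excluded with a warning.
#'
#' @param track_pauses Tibble with columns `n_pauses` and `distance`
#'   (absolute distance travelled, um).
#' @return One-row tibble: `weighted_mean`, `weighted_sd`, `weighted_sem`
#'   (1/um) and `n_tracks`.
#' @export
spatial_pause_frequency <- function(track_pauses) {
  bad <- track_pauses$distance <= 0
  if (any(bad)) {
    rlang::warn(sprintf("excluding %d track(s) with zero distance", sum(bad)))
    track_pauses <- track_pauses[!bad, , drop = FALSE]
  }
  if (nrow(track_pauses) == 0) rlang::abort("no tracks with positive distance")
  xf <- track_pauses$n_pauses / track_pauses$distance
  m <- weighted_moments(xf, track_pauses$distance)
  tibble::tibble(weighted_mean = m[["mean"]], weighted_sd = m[["sd"]],
                 weighted_sem = m[["sem"]], n_tracks = as.integer(m[["n"]]))
}

#' Per-track pause counts and distances from a segment table
#'
#' Summarises a segment table into the input of
#' [spatial_pause_frequency()]: the pause count and the total absolute
#' distance travelled during runs, per track.
#'
#' @param segments Segment tibble with `track_id`.
#' @return Tibble with `track_id`, `n_pauses`, `distance` (um).
#' @export
track_pause_table <- function(segments) {
  tibble::as_tibble(segments) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(
      n_pauses = sum(.data$kind == "pause"),
      distance = sum(abs(.data$distance_nm[.data$kind != "pause"])) / 1000,
      .groups = "drop")
}

#' Resample simulated tracks to experimental durations
#'
#' Simulated tracks are typically longer than experimental ones (no
#' microtubule ends in silico).  Each simulated track is chopped
#' sequentially into pieces whose durations are drawn with replacement
#' from `target_durations`; a trailing remainder shorter than the drawn
#' duration is discarded.  Every piece carries weight
#' `1 / (number of pieces)` so that piece-level statistics match the
#' experimental duration distribution.
#'
#' @param tracks Tibble with `track_id`, `t_s`, `x_nm` (uniform sampling).
#' @param target_durations Positive durations to draw from (s).
#' @param seed Optional integer seed for the duration draws.
#' @return Tibble of track pieces: `piece_id`, `track_id`, `t_s`
#'   (re-zeroed), `x_nm`, further per-sample columns preserved, the drawn
#'   `piece_duration_s`, and `weight` (identical within a piece, summing
#'   to 1 over pieces).
#' @export
resample_to_durations <- function(tracks, target_durations, seed = NULL) {
  stopifnot(all(target_durations > 0))
  if (!is.null(seed)) set.seed(seed)
  pieces <- list()
  pid <- 0L
  for (id in unique(tracks$track_id)) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    t0 <- min(tr$t_s)
    total <- max(tr$t_s) - t0
    used <- 0
    repeat {
      dur <- sample(target_durations, 1)
      if (used + dur > total + 1e-9) break
      pid <- pid + 1L
      keep <- tr$t_s >= t0 + used - 1e-9 & tr$t_s <= t0 + used + dur + 1e-9
      pc <- tr[keep, , drop = FALSE]
      pc$piece_id <- pid
      pc$piece_duration_s <- dur
      pc$t_s <- pc$t_s - min(pc$t_s)
      pieces[[pid]] <- pc
      used <- used + dur
    }
  }
  if (length(pieces) == 0)
    return(tibble::tibble(piece_id = integer(), track_id = integer(),
                          t_s = numeric(), x_nm = numeric(),
                          piece_duration_s = numeric(), weight = numeric()))
  out <- dplyr::bind_rows(pieces)
  out$weight <- 1 / length(pieces)
  dplyr::relocate(out, "piece_id")
}

#' Vesicle elongation index
#'
#' Shape measure of a fitted vesicle: the ratio of the difference to the
#' sum of the long and short axes; 0 for a sphere, approaching 1 for
#' strongly elongated shapes.
#'
#' @param long_axis,short_axis Axis lengths (nm), `long >= short > 0`.
#' @return Elongation index in `[0, 1)`.
#' @export
elongation_index <- function(long_axis, short_axis) {
  if (any(short_axis <= 0) || any(long_axis < short_axis))
    rlang::abort("axes must satisfy long >= short > 0")
  (long_axis - short_axis) / (long_axis + short_axis)
}
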