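#' Tag pauses and instantaneous reversals
#'
#' Adds the pause taxonomy to a segment table: a pause flanked by runs of
#' opposite sign is a *reversal pause*, any other pause is a *non-reversal
#' pause*; two adjacent runs of opposite sign with no pause in between mark
#' an *instantaneous reversal* (flagged on the second run).
#'
#' @param segments Segment tibble for one track (see
#'   [postprocess_segments()]).
#' @return The segments with `pause_type` (`reversal`, `non_reversal` or
#'   `NA` for runs) and logical `instant_reversal` columns.
#' @export
tag_pauses <- function(segments) {
  k <- segments$kind
  run_sign <- ifelse(k == "run_pos", 1L, ifelse(k == "run_neg", -1L, 0L))
  n <- length(k)
  pause_type <- rep(NA_character_, n)
  instant <- rep(FALSE, n)
  # sign of the nearest run before/after each segment
  prev_run <- integer(n); nxt_run <- integer(n)
  last <- 0L
  for (i in seq_len(n)) { prev_run[i] <- last; if (run_sign[i] != 0) last <- run_sign[i] }
  nxt <- 0L
  for (i in rev(seq_len(n))) { nxt_run[i] <- nxt; if (run_sign[i] != 0) nxt <- run_sign[i] }
  for (i in seq_len(n)) {
    if (k[i] == "pause") {
      pause_type[i] <- if (prev_run[i] != 0 && nxt_run[i] != 0 &&
                           prev_run[i] != nxt_run[i]) "reversal" else "non_reversal"
    } else if (i > 1 && run_sign[i] != 0 && run_sign[i - 1] != 0 &&
               run_sign[i] != run_sign[i - 1]) {
      instant[i] <- TRUE
    }
  }
  segments$pause_type <- pause_type
  segments$instant_reversal <- instant
  segments
}

#' Classify a segmented track
#'
#' A track is a *minus* track when it contains at least one negative run
#' and no positive run, a *plus* track in the mirrored case, a *reversal*
#' track when it contains runs of both signs, and *stationary* when it
#' contains no run at all.
#'
#' @param segments Segment tibble for one track.
#' @return One-row tibble: `label`, run/pause counts, reversal-pause,
#'   non-reversal-pause and instantaneous-reversal counts.
#' @export
classify_track <- function(segments) {
  if (is.null(segments) || nrow(segments) == 0)
    rlang::abort("cannot classify an empty segment list")
  segments <- tag_pauses(segments)
  n_pos <- sum(segments$kind == "run_pos")
  n_neg <- sum(segments$kind == "run_neg")
  label <- if (n_pos == 0 && n_neg == 0) "stationary"
    else if (n_pos > 0 && n_neg > 0) "reversal"
    else if (n_pos > 0) "plus" else "minus"
  tibble::tibble(
    label = factor(label, levels = c("minus", "plus", "reversal",
                                     "stationary")),
    n_runs_pos = n_pos, n_runs_neg = n_neg,
    n_pauses = sum(segments$kind == "pause"),
    n_reversal_pauses = sum(segments$pause_type == "reversal", na.rm = TRUE),
    n_nonreversal_pauses = sum(segments$pause_type == "non_reversal",
                               na.rm = TRUE),
    n_instant_reversals = sum(segments$instant_reversal))
}

#' Classify all tracks of a segment table
#'
#' @param segments Segment tibble with a `track_id` column.
#' @return Tibble with one row per track (see [classify_track()]).
#' @export
classify_tracks <- function(segments) {
  dplyr::bind_rows(purrr::map(split(tibble::as_tibble(segments),
                                    segments$track_id), function(s) {
    out <- classify_track(s)
    out$track_id <- s$track_id[1]
    out
  })) |> dplyr::relocate("track_id")
}

#' Fractions of track classes
#'
#' @param classifications Output of [classify_tracks()].
#' @return Tibble with `label`, `n` and `fraction` (all four classes kept,
#'   zeros included).
#' @export
class_fractions <- function(classifications) {
  counts <- table(classifications$label)
  tibble::tibble(label = names(counts), n = as.integer(counts),
                 fraction = as.numeric(counts) / sum(counts))
}
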