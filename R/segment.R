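#' Annealing configuration for change-point segmentation
#'
#' Settings of the simulated-annealing minimisation of the segmentation
#' cost `H = E_err + mu_cost * N_cp`, where `E_err` is the summed squared
#' residual (nm^2) of the piecewise-linear fit and `N_cp` the number of
#' interior change points.  Starting from `n_cp_init` equally spaced
#' change points, `equil_updates` Metropolis updates are run at
#' `beta_init`, then `cooling_updates` at each tenfold increase of beta up
#' to `beta_final`.
#'
#' @param mu_cost Cost per interior change point (nm^2).
#' @param beta_init,beta_final Inverse-temperature schedule endpoints.
#' @param equil_updates Updates during equilibration.
#' @param cooling_updates Updates per cooling decade.
#' @param eps_x,eps_t Amplitudes of change-point shift proposals (nm, s);
#'   `eps_t = NULL` uses two sampling intervals.
#' @param move_probs Probabilities of the shift / add / remove moves.
#' @param n_cp_init Initial interior change-point count; `NULL` uses
#'   `max(1, floor(track duration / 5 s))`.
#' @param check_every Cross-check the incrementally updated cost against a
#'   full recomputation every this many updates (0 disables).
#' @param min_run_speed Segments whose endpoint-to-endpoint speed is below
#'   this (nm/s) are pauses.
#' @param min_run_distance Runs shorter than this (nm) become pauses.
#' @param merge_same_kind Merge adjacent same-kind segments after labeling.
#' @return A list of class `anneal_config`.
#' @export
anneal_config <- function(mu_cost = 10000, beta_init = 0.005,
                          beta_final = 50, equil_updates = 4000,
                          cooling_updates = 1000, eps_x = 200, eps_t = NULL,
                          move_probs = c(shift = 0.8, add = 0.1,
                                         remove = 0.1),
                          n_cp_init = NULL, check_every = 100,
                          min_run_speed = 100, min_run_distance = 500,
                          merge_same_kind = FALSE) {
  stopifnot(abs(sum(move_probs) - 1) < 1e-9, beta_final >= beta_init,
            mu_cost >= 0)
  structure(list(mu_cost = mu_cost, beta_init = beta_init,
                 beta_final = beta_final, equil_updates = equil_updates,
                 cooling_updates = cooling_updates, eps_x = eps_x,
                 eps_t = eps_t, move_probs = move_probs,
                 n_cp_init = n_cp_init, check_every = check_every,
                 min_run_speed = min_run_speed,
                 min_run_distance = min_run_distance,
                 merge_same_kind = merge_same_kind),
            class = "anneal_config")
}

#' Evaluate a piecewise-linear segmentation
#'
#' Linear interpolation between the change points bracketing each query
#' time.
#'
#' @param cp_t,cp_x Change-point coordinates (strictly increasing times).
#' @param t Query times within `[min(cp_t), max(cp_t)]`.
#' @return Fitted positions (nm).
#' @export
eval_piecewise <- function(cp_t, cp_x, t) {
  stopifnot(length(cp_t) == length(cp_x), length(cp_t) >= 2,
            all(diff(cp_t) > 0))
  if (any(t < cp_t[1] - 1e-9 | t > cp_t[length(cp_t)] + 1e-9))
    rlang::abort("query times outside the change-point range")
  stats::approx(cp_t, cp_x, xout = t, rule = 2)$y
}

#' Segmentation cost
#'
#' `H = sum_i (x_i - f(t_i))^2 + mu_cost * N_cp` with `f` the
#' piecewise-linear interpolant through the change points and `N_cp` the
#' number of interior change points.
#'
#' @param track Tibble with `t_s` and `x_nm`.
#' @inheritParams eval_piecewise
#' @param mu_cost Cost per interior change point (nm^2).
#' @return The cost H (nm^2).
#' @export
segment_cost <- function(track, cp_t, cp_x, mu_cost = 10000) {
  f <- eval_piecewise(cp_t, cp_x, track$t_s)
  sum((track$x_nm - f)^2) + mu_cost * (length(cp_t) - 2)
}

#' Propose a change-point update
#'
#' One Metropolis proposal of the annealer: shift a random interior change
#' point by a uniform perturbation, add a change point at a random data
#' point of the track, or remove a random interior change point.  Proposals
#' that break time ordering (or a removal with no interior points) return
#' the configuration unchanged with `rejected = TRUE`.
#'
#' @param track Tibble with `t_s` and `x_nm`.
#' @param cp_t,cp_x Current change points (endpoints pinned).
#' @param config An [anneal_config()].
#' @return List with `cp_t`, `cp_x`, `move`, `rejected`, and `d_ncp`.
#' @export
propose_change_points <- function(track, cp_t, cp_x,
                                  config = anneal_config()) {
  eps_t <- config$eps_t %||% (2 * stats::median(diff(track$t_s)))
  n_cp <- length(cp_t) - 2
  move <- sample(names(config$move_probs), 1, prob = config$move_probs)
  rejected <- FALSE
  d_ncp <- 0L
  if (move == "shift") {
    if (n_cp == 0) {
      rejected <- TRUE
    } else {
      k <- sample.int(n_cp, 1) + 1
      tn <- cp_t[k] + eps_t * (stats::runif(1) - 0.5)
      xn <- cp_x[k] + config$eps_x * (stats::runif(1) - 0.5)
      if (tn <= cp_t[k - 1] || tn >= cp_t[k + 1]) {
        rejected <- TRUE
      } else {
        cp_t[k] <- tn; cp_x[k] <- xn
      }
    }
  } else if (move == "add") {
    j <- sample.int(nrow(track), 1)
    tn <- track$t_s[j]
    if (any(abs(cp_t - tn) < 1e-12)) {
      rejected <- TRUE
    } else {
      pos <- findInterval(tn, cp_t)
      cp_t <- append(cp_t, tn, after = pos)
      cp_x <- append(cp_x, track$x_nm[j], after = pos)
      d_ncp <- 1L
    }
  } else {
    if (n_cp == 0) {
      rejected <- TRUE
    } else {
      k <- sample.int(n_cp, 1) + 1
      cp_t <- cp_t[-k]; cp_x <- cp_x[-k]
      d_ncp <- -1L
    }
  }
  list(cp_t = cp_t, cp_x = cp_x, move = move, rejected = rejected,
       d_ncp = d_ncp)
}

#' Anneal the change points of one track
#'
#' Minimises the segmentation cost by simulated annealing (see
#' [anneal_config()] for the schedule).  Uses the current RNG state; seed
#' with `set.seed()` or use [segment_track()] which manages seeding.
#'
#' @param track Tibble with `t_s` and `x_nm` (>= 2 samples).
#' @param config An [anneal_config()].
#' @return An object of class `tug_changepoints`: list with `cp` (tibble
#'   `t_s`, `x_nm`), `H`, `E_err`, `n_cp`, `acceptance_rate`, and
#'   `max_incremental_rel_err` (incremental-cost bookkeeping check).
#' @export
anneal_track <- function(track, config = anneal_config()) {
  if (nrow(track) < 2) rlang::abort("track needs at least 2 samples")
  dt <- stats::median(diff(track$t_s))
  eps_t <- config$eps_t %||% (2 * dt)
  duration <- max(track$t_s) - min(track$t_s)
  n_init <- config$n_cp_init %||% max(1L, floor(duration / 5))
  res <- cpp_anneal(track$t_s, track$x_nm, config$mu_cost, config$eps_x,
                    eps_t, as.integer(n_init),
                    config$move_probs[["shift"]],
                    config$move_probs[["add"]],
                    config$move_probs[["remove"]],
                    as.integer(config$equil_updates),
                    as.integer(config$cooling_updates),
                    config$beta_init, config$beta_final,
                    as.integer(config$check_every))
  structure(list(cp = tibble::tibble(t_s = res$cp_t, x_nm = res$cp_x),
                 H = res$H, E_err = res$E_err,
                 n_cp = length(res$cp_t) - 2L,
                 acceptance_rate = res$acceptance_rate,
                 max_incremental_rel_err = res$max_incremental_rel_err,
                 mu_cost = config$mu_cost),
            class = "tug_changepoints")
}

#' @export
print.tug_changepoints <- function(x, ...) {
  cat(sprintf("<tug_changepoints> %d interior change points, H = %.1f (E_err = %.1f)\n",
              x$n_cp, x$H, x$E_err))
  invisible(x)
}

#' Label the segments between change points
#'
#' Partitions the sample index range at the interior change-point times and
#' applies the run/pause rules: one-point segments are merged into the
#' following segment (the last into the preceding one); a segment is a
#' pause when the speed between its first and last point is below
#' `min_run_speed` (100 nm/s); a run whose travelled distance is below
#' `min_run_distance` (500 nm) becomes a pause.
#'
#' @param track Tibble with `t_s` and `x_nm`.
#' @param cp_t Change-point times (including endpoints).
#' @param config An [anneal_config()] (thresholds, merge option).
#' @return A tibble of segments: `seg_index`, `kind` (`run_pos`,
#'   `run_neg`, `pause`), index range `i_start`/`i_end`, `t_start`,
#'   `t_end`, `x_start`, `x_end`, `duration_s`, `distance_nm`, `slope_nm_s`,
#'   `mean_velocity_nm_s`.
#' @export
postprocess_segments <- function(track, cp_t, config = anneal_config()) {
  n <- nrow(track)
  interior <- cp_t[cp_t > min(track$t_s) + 1e-12 &
                   cp_t < max(track$t_s) - 1e-12]
  # data index partition: segment j holds samples with t in [b_j, b_{j+1})
  seg_of <- findInterval(track$t_s, sort(interior)) + 1L
  bounds <- split(seq_len(n), seg_of)
  ranges <- purrr::map(bounds, range)
  ranges <- ranges[order(purrr::map_dbl(ranges, 1))]

  # merge one-point segments into the following (last one into preceding)
  i <- 1L
  while (i <= length(ranges)) {
    r <- ranges[[i]]
    if (r[1] == r[2] && length(ranges) > 1) {
      if (i < length(ranges)) {
        ranges[[i + 1]][1] <- r[1]
      } else {
        ranges[[i - 1]][2] <- r[2]
      }
      ranges[[i]] <- NULL
    } else {
      i <- i + 1L
    }
  }

  seg_row <- function(r) {
    i0 <- r[1]; i1 <- r[2]
    dt <- track$t_s[i1] - track$t_s[i0]
    dx <- track$x_nm[i1] - track$x_nm[i0]
    slope <- if (dt > 0) dx / dt else 0
    iv <- if (i1 > i0)
      diff(track$x_nm[i0:i1]) / diff(track$t_s[i0:i1]) else numeric(0)
    tibble::tibble(i_start = i0, i_end = i1, t_start = track$t_s[i0],
                   t_end = track$t_s[i1], x_start = track$x_nm[i0],
                   x_end = track$x_nm[i1], duration_s = dt,
                   distance_nm = dx, slope_nm_s = slope,
                   mean_velocity_nm_s = if (length(iv)) mean(iv) else 0)
  }
  segs <- dplyr::bind_rows(purrr::map(ranges, seg_row))

  # rule 1: slow segments are pauses; rule 2 (500 nm) applies to runs only
  kind <- ifelse(abs(segs$slope_nm_s) < config$min_run_speed, "pause",
                 ifelse(segs$slope_nm_s > 0, "run_pos", "run_neg"))
  kind[kind != "pause" &
       abs(segs$distance_nm) < config$min_run_distance] <- "pause"
  segs$kind <- kind

  if (config$merge_same_kind && nrow(segs) > 1) {
    grp <- cumsum(c(TRUE, segs$kind[-1] != segs$kind[-nrow(segs)]))
    segs <- dplyr::bind_rows(purrr::map(split(segs, grp), function(g) {
      r <- seg_row(c(min(g$i_start), max(g$i_end)))
      r$kind <- g$kind[1]
      r
    }))
  }
  segs$seg_index <- seq_len(nrow(segs))
  dplyr::relocate(segs, "seg_index", "kind")
}

#' Segment one track into runs and pauses
#'
#' Convenience wrapper: anneal the change points, then label the segments.
#'
#' @param track Tibble with `t_s` and `x_nm` (single track).
#' @param config An [anneal_config()].
#' @param seed Optional integer seed for the annealer's RNG stream.
#' @return A tibble of segments (see [postprocess_segments()]) of class
#'   `tug_segments`, with the annealing result in `attr(, "changepoints")`.
#' @export
segment_track <- function(track, config = anneal_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fit <- anneal_track(track, config)
  segs <- postprocess_segments(track, fit$cp$t_s, config)
  if (!is.null(track$track_id)) segs$track_id <- track$track_id[1]
  structure(segs, class = c("tug_segments", class(segs)),
            changepoints = fit, track = track)
}

#' Segment many tracks
#'
#' Applies [segment_track()] per `track_id`, each on its own RNG stream
#' derived from `seed` (reproducible independently of track order).
#'
#' @param tracks Tibble with `track_id`, `t_s`, `x_nm`.
#' @param config An [anneal_config()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A tibble of segments for all tracks (class `tug_segments`).
#' @export
segment_tracks <- function(tracks, config = anneal_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- unique(tracks$track_id)
  stream_seeds <- sample.int(.Machine$integer.max - 1L, length(ids))
  segs <- purrr::map2(ids, stream_seeds, function(id, s) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    if (nrow(tr) < 2) return(NULL)
    segment_track(tr, config, seed = s)
  })
  out <- dplyr::bind_rows(purrr::map(segs, tibble::as_tibble))
  structure(out, class = c("tug_segments", class(out)))
}
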