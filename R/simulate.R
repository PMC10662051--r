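#' Simulation configuration
#'
#' Collects the cargo-level settings of the Gillespie stepping simulation.
#' A cargo carries a team of DDB and KIF16B motors whose total number is
#' drawn per cargo from a Gaussian with standard deviation
#' `sigma_coeff * sqrt(mean)` (see [sample_motor_count()]), split between
#' species binomially (see [split_species()]).  The microtubule is a
#' seven-lane lattice; lanes are drawn from a discrete truncated Gaussian at
#' attachment.  Measurement starts after `relax_time` and the simulation
#' ends at `max_time` or as soon as no motor is attached.
#'
#' @param mean_n_ddb,mean_n_kif Mean motor numbers in the attachment area.
#' @param sigma_coeff Coefficient of the motor-number Gaussian SD.
#' @param atp ATP concentration (mM); `Inf` saturates the Michaelis--Menten
#'   stepping rate.
#' @param kBT Thermal energy (pN nm).
#' @param n_lanes,lane_sigma,lane_cut Lattice lanes and the truncated
#'   Gaussian (SD in lattice units, cut at `lane_cut` sigma) used for lane
#'   choice.
#' @param relax_time Pre-measurement relaxation window (s).
#' @param max_time Total simulated time (s).
#' @param sample_interval Sampling interval of the recorded track (s);
#'   0.1 s mirrors 10-fps imaging (0.3 s mirrors time-lapse mode).
#' @param metropolis_n,metropolis_step Number and amplitude (nm) of
#'   Metropolis proposals used to thermalise the cargo after each event
#'   (the cargo is first placed at its force-balance position).
#' @param bell_literal_sign Use the decreasing detachment exponent (see
#'   [detachment_rate()]).
#' @param stall_target Stepping rate pinned at the stall force (1/s).
#' @param fixed_counts Optional integer vector `c(n_ddb, n_kif)` bypassing
#'   the stochastic motor-number draw (controlled experiments).
#' @param validate Assert lattice exclusion after every event (slower).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(mean_n_ddb = 8, mean_n_kif = 14, sigma_coeff = 1.0683,
                       atp = 2.5, kBT = 4.11, n_lanes = 7, lane_sigma = 1,
                       lane_cut = 3, relax_time = 4, max_time = 80,
                       sample_interval = 0.1, metropolis_n = 100,
                       metropolis_step = 2, bell_literal_sign = FALSE,
                       stall_target = 0.1, fixed_counts = NULL,
                       validate = FALSE) {
  stopifnot(sample_interval > 0, max_time > relax_time,
            mean_n_ddb >= 0, mean_n_kif >= 0, n_lanes == 2 * lane_cut + 1)
  structure(list(
    mean_n_ddb = mean_n_ddb, mean_n_kif = mean_n_kif,
    sigma_coeff = sigma_coeff, atp = atp, kBT = kBT, n_lanes = n_lanes,
    lane_sigma = lane_sigma, lane_cut = as.integer(lane_cut),
    relax_time = relax_time, max_time = max_time,
    sample_interval = sample_interval,
    metropolis_n = as.integer(metropolis_n),
    metropolis_step = metropolis_step,
    bell_literal_sign = bell_literal_sign, stall_target = stall_target,
    fixed_counts = fixed_counts, validate = validate), class = "sim_config")
}

#' Draw the total motor number of a cargo
#'
#' The number of motors on a cargo is drawn from a Gaussian with mean `mu`
#' and standard deviation `sigma_coeff * sqrt(mu)`, rounded to the nearest
#' integer and clipped at zero.
#'
#' @param mu Mean motor number (>= 0).
#' @param sigma_coeff Coefficient of the SD--mean relation.
#' @param n Number of draws.
#' @return Integer vector of motor counts.
#' @export
sample_motor_count <- function(mu, sigma_coeff = 1.0683, n = 1) {
  if (!is.numeric(mu) || length(mu) != 1 || is.na(mu) || mu < 0)
    rlang::abort("`mu` must be a single non-negative number")
  pmax(0L, as.integer(round(stats::rnorm(n, mu, sigma_coeff * sqrt(mu)))))
}

#' Split a motor count between species
#'
#' Given a total motor number, the DDB count is binomial with probability
#' `mean_d / (mean_d + mean_k)`; the rest are KIF16B.
#'
#' @param total Total motor count (>= 0).
#' @param mean_d,mean_k Mean numbers of DDB and KIF16B.
#' @return Integer vector `c(n_ddb, n_kif)`.
#' @export
split_species <- function(total, mean_d, mean_k) {
  stopifnot(total >= 0)
  if (total > 0 && mean_d + mean_k <= 0)
    rlang::abort("cannot split motors: both species means are zero")
  if (total == 0) return(c(n_ddb = 0L, n_kif = 0L))
  nd <- stats::rbinom(1, total, mean_d / (mean_d + mean_k))
  c(n_ddb = nd, n_kif = as.integer(total) - nd)
}

#' Draw activity classes for attaching motors
#'
#' Every attachment event draws the motor's class afresh: inactive with
#' probability `frac_inactive`, diffusive with `frac_diffusive`, otherwise
#' active.
#'
#' @param params A [motor_params()] object.
#' @param n Number of draws.
#' @return Factor with levels `active`, `inactive`, `diffusive`.
#' @export
assign_activity <- function(params, n = 1) {
  u <- stats::runif(n)
  cls <- ifelse(u < params$frac_inactive, "inactive",
                ifelse(u < params$frac_inactive + params$frac_diffusive,
                       "diffusive", "active"))
  factor(cls, levels = c("active", "inactive", "diffusive"))
}

#' Draw a protofilament lane
#'
#' Lanes are integers in `[-cut, cut]` with probabilities proportional to
#' the standard-normal density at the lane index (a discrete truncated
#' Gaussian peaked on the central protofilament).
#'
#' @param n Number of draws.
#' @param sigma SD of the Gaussian in lattice units.
#' @param cut Truncation (lanes beyond `cut * sigma` are excluded).
#' @return Integer lanes.
#' @export
sample_lane <- function(n = 1, sigma = 1, cut = 3) {
  lanes <- seq.int(-cut, cut)
  p <- stats::dnorm(lanes, 0, sigma)
  sample(lanes, n, replace = TRUE, prob = p / sum(p))
}

#' Total unsigned force on the cargo
#'
#' The cargo force is the sum of the absolute values of the spring forces
#' of all attached motors.
#'
#' @param head_pos Attached motor head positions (nm).
#' @param cargo_pos Cargo position (nm).
#' @param kappa,rest_length Per-motor stiffness and rest length (recycled).
#' @return Total force (pN).
#' @export
cargo_force <- function(head_pos, cargo_pos, kappa, rest_length) {
  if (length(head_pos) == 0) return(0)
  sum(abs(motor_force(head_pos - cargo_pos, kappa, rest_length)))
}

#' Relax the cargo in the potential of its motor springs
#'
#' The total spring energy is convex and piecewise quadratic in the cargo
#' position, so the cargo is first placed at the force-balance point nearest
#' its current position and then thermalised with `n_proposals` Metropolis
#' moves of uniform amplitude `step_size`.  With no attached motors the
#' position is unchanged.
#'
#' @inheritParams cargo_force
#' @param x0 Current cargo position (nm).
#' @param kBT Thermal energy (pN nm); `0` gives pure energy descent.
#' @param n_proposals,step_size Metropolis settings.
#' @return A list with `x`, `energy_initial`, `energy_final`, `force`.
#' @export
relax_cargo <- function(head_pos, kappa, rest_length, x0, kBT = 4.11,
                        n_proposals = 100, step_size = 2) {
  if (length(head_pos) == 0)
    return(list(x = x0, energy_initial = 0, energy_final = 0, force = 0))
  k <- rep_len(kappa, length(head_pos))
  L <- rep_len(rest_length, length(head_pos))
  cpp_relax_cargo(head_pos, k, L, x0, kBT, n_proposals, step_size)
}

motor_params_for_cpp <- function(p) {
  if (is.null(p$vmax_fixed) || !is.finite(p$vmax_fixed))
    p$vmax_fixed <- NA_real_
  p
}

#' Simulate one cargo
#'
#' Runs the Gillespie stepping simulation for a single cargo: motors
#' attach with constant rates to the lattice site nearest the cargo on a
#' Gaussian-drawn lane (aborted if occupied), active motors step with the
#' force- and ATP-dependent rate (backward creep above stall), diffusive
#' motors hop towards their spring equilibrium, all motors detach with
#' Bell-type rates, and the cargo re-equilibrates in the spring potential
#' after every event.  Measurement starts after `relax_time`; the run ends
#' at `max_time` or when no motor is attached.
#'
#' Uses the current RNG state; seed with `set.seed()` for reproducibility
#' (or use [simulate_cargoes()] which manages per-track streams).
#'
#' @param config A [sim_config()].
#' @param ddb,kif16b [motor_params()] for the two species.
#' @param track_id Identifier stored in the output.
#' @return A list with `track` (tibble: `track_id`, `t_s`, `x_nm`,
#'   `n_att_ddb`, `n_att_kif`, `f_cargo_pN`), `runs` (tibble of
#'   attachment episodes), `counts`, and `status`.
#' @export
simulate_cargo <- function(config = sim_config(), ddb = ddb_params(),
                           kif16b = kif16b_params(), track_id = 1L) {
  if (!is.null(config$fixed_counts)) {
    counts <- as.integer(config$fixed_counts)
  } else {
    tot <- sample_motor_count(config$mean_n_ddb + config$mean_n_kif,
                              config$sigma_coeff)
    counts <- if (tot == 0) c(0L, 0L) else
      split_species(tot, config$mean_n_ddb, config$mean_n_kif)
  }
  cfg <- config
  cfg$n_ddb <- counts[[1]]
  cfg$n_kif <- counts[[2]]
  res <- cpp_simulate_cargo(motor_params_for_cpp(unclass(ddb)),
                            motor_params_for_cpp(unclass(kif16b)),
                            unclass(cfg))
  track <- tibble::tibble(
    track_id = track_id, t_s = res$t, x_nm = res$x,
    n_att_ddb = res$n_att_ddb, n_att_kif = res$n_att_kif,
    f_cargo_pN = res$f_cargo)
  runs <- tibble::as_tibble(res$runs)
  runs$species <- c("DDB", "KIF16B")[runs$species + 1L]
  runs$activity <- c("active", "inactive", "diffusive")[runs$activity + 1L]
  runs$track_id <- rep(track_id, nrow(runs))
  list(track = track, runs = runs,
       counts = c(n_ddb = counts[[1]], n_kif = counts[[2]]),
       status = res$status)
}

#' Simulate a population of cargoes
#'
#' Repeats [simulate_cargo()] for `n_cargoes` cargoes, each on its own RNG
#' stream derived from `seed` so that individual tracks are reproducible
#' independently of how many are simulated.
#'
#' @inheritParams simulate_cargo
#' @param n_cargoes Number of cargoes.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A tibble of tracks (class `tug_tracks`) with the per-cargo run
#'   episodes in `attr(, "runs")` and motor counts in `attr(, "counts")`.
#' @export
simulate_cargoes <- function(n_cargoes, config = sim_config(),
                             ddb = ddb_params(), kif16b = kif16b_params(),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stream_seeds <- sample.int(.Machine$integer.max - 1L, n_cargoes)
  out <- purrr::map(seq_len(n_cargoes), function(i) {
    set.seed(stream_seeds[i])
    simulate_cargo(config, ddb, kif16b, track_id = i)
  })
  tracks <- dplyr::bind_rows(purrr::map(out, "track"))
  structure(tracks, class = c("tug_tracks", class(tracks)),
            runs = dplyr::bind_rows(purrr::map(out, "runs")),
            counts = dplyr::bind_rows(purrr::map(out, ~tibble::tibble(
              n_ddb = .x$counts[["n_ddb"]], n_kif = .x$counts[["n_kif"]],
              status = .x$status))),
            config = config)
}

#' Simulate single-molecule runs of a lone motor
#'
#' The single-molecule limit of the stepping model: one motor walks on the
#' lattice under zero load (no cargo, no opposing team), stepping at its
#' zero-load rate and detaching at the force-free rate, as in a
#' single-molecule motility assay.  Positions are sampled at the imaging
#' frame interval and carry Gaussian localization noise.
#'
#' @param params A [motor_params()] object.
#' @param n_runs Number of independent motors.
#' @param vmax Maximal velocity used for every motor (nm/s); default the
#'   species median.
#' @param atp ATP concentration (mM), `Inf` for saturating.
#' @param sample_interval Frame interval (s).
#' @param noise_sd Localization noise SD added to sampled positions (nm);
#'   30 nm reflects single-fluorophore tracking precision.
#' @param max_time Cap on a single run's duration (s).
#' @param seed Optional integer seed.
#' @return A list with `runs` (tibble: `run`, `length_nm`, `duration_s`)
#'   and `tracks` (tibble: `run`, `t_s`, `x_nm`).
#' @export
simulate_single_molecules <- function(params, n_runs, vmax = exp(params$vmax_meanlog),
                                      atp = Inf, sample_interval = 0.1,
                                      noise_sd = 30, max_time = 600,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rate0 <- schnitzer_rate_r(0, atp, vmax / params$step_size,
                            params$schnitzer, 0, 4.11)
  res <- cpp_single_molecules(as.integer(n_runs), rate0,
                              params$detach_rate_active, params$step_size,
                              params$polarity, sample_interval, max_time)
  tracks <- tibble::tibble(run = res$frame_run, x_nm = res$frame_x)
  tracks <- dplyr::mutate(dplyr::group_by(tracks, .data$run),
                          t_s = (dplyr::row_number() - 1) * sample_interval)
  tracks <- dplyr::ungroup(tracks)
  if (noise_sd > 0)
    tracks$x_nm <- tracks$x_nm + stats::rnorm(nrow(tracks), 0, noise_sd)
  list(runs = tibble::tibble(run = seq_len(n_runs),
                             length_nm = res$run_length,
                             duration_s = res$run_duration),
       tracks = tracks[, c("run", "t_s", "x_nm")])
}
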