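# Shared fixtures: all synthetic, built in code at test time.

# run-pause-run blueprint with segment durations >= 3 s
rpr_blueprint <- function(v1 = 800, v2 = -800, run_s = 4, pause_s = 4,
                          noise_sd = 20, dt = 0.1) {
  track_blueprint(change_times = c(0, run_s, run_s + pause_s),
                  velocities = c(v1, 0, v2),
                  duration = 2 * run_s + pause_s,
                  noise_sd = noise_sd, sample_interval = dt)
}

# straight noisy track
linear_track <- function(v = 500, duration = 10, noise_sd = 0, dt = 0.1,
                         track_id = 1L) {
  t <- seq(0, duration, by = dt)
  tibble::tibble(track_id = track_id, t_s = t,
                 x_nm = v * t + stats::rnorm(length(t), 0, noise_sd))
}

# build a segment tibble from a kind sequence (for classification tests)
segments_from_kinds <- function(kinds) {
  n <- length(kinds)
  tibble::tibble(seg_index = seq_len(n), kind = kinds,
                 i_start = seq_len(n), i_end = seq_len(n) + 1L,
                 t_start = seq_len(n) - 1, t_end = seq_len(n),
                 x_start = 0, x_end = 0, duration_s = 1,
                 distance_nm = ifelse(kinds == "run_pos", 1000,
                                      ifelse(kinds == "run_neg", -1000, 10)),
                 slope_nm_s = ifelse(kinds == "run_pos", 1000,
                                     ifelse(kinds == "run_neg", -1000, 10)),
                 mean_velocity_nm_s = 0)
}

# single-motor engine configuration: exactly one motor of one species,
# always active, fixed maximal velocity, no thermal cargo jitter
single_motor_setup <- function(species = c("kif", "ddb"), vmax = 800,
                               detach_force = Inf, max_time = 400) {
  species <- match.arg(species)
  cfg <- sim_config(relax_time = 0, max_time = max_time,
                    metropolis_n = 0, atp = Inf,
                    fixed_counts = if (species == "kif") c(0L, 1L)
                                   else c(1L, 0L))
  kif <- kif16b_params(frac_inactive = 0, vmax_fixed = vmax,
                       detach_force = detach_force)
  ddb <- ddb_params(frac_inactive = 0, frac_diffusive = 0,
                    vmax_fixed = vmax, detach_force = detach_force)
  list(cfg = cfg, ddb = ddb, kif = kif)
}
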