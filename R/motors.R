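#' Per-species motor parameters
#'
#' Bundles the kinetic and mechanical constants of one motor species into a
#' validated list.  Motors are modelled as Hookean springs with a dead zone:
#' a motor whose head is within `rest_length` of the cargo exerts no force;
#' beyond that the spring engages with stiffness `kappa`.  Stepping follows a
#' Michaelis--Menten rate in ATP whose catalytic and binding constants are
#' Boltzmann-distributed in the resisting load (see [stepping_rate()]),
#' detachment follows a Bell-type exponential in load (see
#' [detachment_rate()]), and a configurable fraction of motors is inactive
#' (strongly bound, non-stepping) or -- for DDB -- diffusive.
#'
#' The individual maximal (zero-load) velocity of each attaching motor is
#' drawn from a log-normal distribution parameterised by `vmax_meanlog` and
#' `vmax_sdlog`, mirroring the spread of measured single-molecule
#' instantaneous velocities; set `vmax_fixed` to a finite value to give every
#' motor the same maximal velocity (useful for calibration runs).
#'
#' @param species_name Label, e.g. `"KIF16B"` or `"DDB"`.
#' @param kappa Spring stiffness (pN/nm).
#' @param rest_length Spring rest length / dead-zone half width L (nm).
#' @param stall_force Stall force magnitude F_s (pN).
#' @param detach_force Detachment force scale F_d of the Bell law (pN).
#' @param attach_rate Attachment rate k_a (1/s) per motor in the attachment
#'   area.
#' @param detach_rate_active Force-free detachment rate of active motors
#'   (1/s).
#' @param detach_rate_inactive Force-free detachment rate of inactive
#'   (strongly bound) motors (1/s).
#' @param back_velocity Constant backward creep velocity v_b above stall
#'   (nm/s).
#' @param step_size Lattice step d (nm).
#' @param frac_inactive,frac_diffusive Probabilities that a freshly attached
#'   motor is inactive / diffusive; must sum to at most 1.
#' @param diffusive_rate Unloaded hopping rate s_0 of diffusive motors (1/s).
#' @param schnitzer List with elements `k_b0` (1/(s mM)), `p_b`, `q_b`,
#'   `p_cat`, `q_cat`; `p + q` must equal 1 for each pair.
#' @param polarity `+1` for plus-end directed motors (KIF16B), `-1` for
#'   minus-end directed motors (DDB).
#' @param vmax_meanlog,vmax_sdlog Log-normal parameters of the individual
#'   maximal velocity (nm/s).
#' @param vmax_fixed Finite value to pin every motor's maximal velocity
#'   (nm/s); `NA` (default) draws from the log-normal.
#'
#' @return An object of class `motor_params` (a named list).
#' @seealso [kif16b_params()], [ddb_params()] for documented defaults.
#' @export
motor_params <- function(species_name, kappa, rest_length, stall_force,
                         detach_force, attach_rate, detach_rate_active,
                         detach_rate_inactive, back_velocity, step_size,
                         frac_inactive, frac_diffusive, diffusive_rate,
                         schnitzer, polarity, vmax_meanlog, vmax_sdlog,
                         vmax_fixed = NA_real_) {
  p <- list(
    species_name = species_name, kappa = kappa, rest_length = rest_length,
    stall_force = stall_force, detach_force = detach_force,
    attach_rate = attach_rate, detach_rate_active = detach_rate_active,
    detach_rate_inactive = detach_rate_inactive,
    back_velocity = back_velocity, step_size = step_size,
    frac_inactive = frac_inactive, frac_diffusive = frac_diffusive,
    diffusive_rate = diffusive_rate, schnitzer = schnitzer,
    polarity = as.integer(polarity), vmax_meanlog = vmax_meanlog,
    vmax_sdlog = vmax_sdlog, vmax_fixed = vmax_fixed)
  validate_motor_params(p)
  structure(p, class = "motor_params")
}

validate_motor_params <- function(p) {
  nonneg <- c("kappa", "rest_length", "stall_force", "attach_rate",
              "detach_rate_active", "detach_rate_inactive", "back_velocity",
              "step_size", "diffusive_rate")
  for (f in nonneg) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || is.na(p[[f]]) ||
        p[[f]] < 0)
      rlang::abort(sprintf("`%s` must be a single non-negative number", f))
  }
  if (!(p$detach_force > 0))
    rlang::abort("`detach_force` must be positive")
  if (p$frac_inactive < 0 || p$frac_diffusive < 0 ||
      p$frac_inactive + p$frac_diffusive > 1 + 1e-12)
    rlang::abort("`frac_inactive` + `frac_diffusive` must lie in [0, 1]")
  sc <- p$schnitzer
  if (abs(sc$p_b + sc$q_b - 1) > 1e-9 || abs(sc$p_cat + sc$q_cat - 1) > 1e-9)
    rlang::abort("schnitzer weights must satisfy p_b + q_b = 1 and p_cat + q_cat = 1")
  if (!p$polarity %in% c(-1L, 1L))
    rlang::abort("`polarity` must be +1 or -1")
  if (p$polarity == 1L && p$frac_diffusive > 0)
    rlang::abort("the diffusive class is defined for DDB only (polarity -1)")
  invisible(p)
}

#' @export
print.motor_params <- function(x, ...) {
  cat(sprintf("<motor_params> %s (polarity %+d)\n", x$species_name,
              x$polarity))
  cat(sprintf("  spring: kappa = %g pN/nm, L = %g nm\n", x$kappa,
              x$rest_length))
  cat(sprintf("  forces: F_s = %g pN, F_d = %g pN\n", x$stall_force,
              x$detach_force))
  cat(sprintf("  rates:  k_a = %g /s, k_d0 = %g /s (inactive %g /s)\n",
              x$attach_rate, x$detach_rate_active, x$detach_rate_inactive))
  cat(sprintf("  classes: %g%% inactive, %g%% diffusive\n",
              100 * x$frac_inactive, 100 * x$frac_diffusive))
  cat(sprintf("  vmax: median %g nm/s (lognormal sdlog %g)\n",
              exp(x$vmax_meanlog), x$vmax_sdlog))
  invisible(x)
}

#' Log-normal parameters from a median and interquartile range
#'
#' Matches `meanlog` and `sdlog` so that the log-normal distribution has the
#' requested median and interquartile range.
#'
#' @param median,iqr Target median and IQR (same units).
#' @return Named numeric vector with `meanlog` and `sdlog`.
#' @export
lnorm_from_median_iqr <- function(median, iqr) {
  stopifnot(median > 0, iqr > 0)
  # q75 - q25 = median * (exp(z s) - exp(-z s)) with z = qnorm(0.75)
  sdlog <- asinh(iqr / (2 * median)) / stats::qnorm(0.75)
  c(meanlog = log(median), sdlog = sdlog)
}

# shared Michaelis-Menten load-sharing constants (ATP binding ~ 1.35 /uM/s,
# load borne mostly by the catalytic transition)
default_schnitzer <- function() {
  list(k_b0 = 1350, p_b = 0.05, q_b = 0.95, p_cat = 0.5, q_cat = 0.5)
}

#' Default KIF16B parameters
#'
#' Literature-plausible constants for the plus-end directed kinesin-3
#' KIF16B.  The force-free detachment rate is derived from the measured
#' single-molecule medians (velocity 800 nm/s, run length 0.63 um) via
#' `k_d0 = v ln 2 / L_med`, so that exponential run lengths reproduce the
#' measured median; the individual maximal velocity distribution is
#' log-normal matched to the single-molecule median and IQR
#' (0.80 +/- 0.63 um/s).
#'
#' @param ... Named overrides for any [motor_params()] field.
#' @return A `motor_params` object.
#' @export
kif16b_params <- function(...) {
  ln <- lnorm_from_median_iqr(800, 630)
  defaults <- list(
    species_name = "KIF16B", kappa = 0.3, rest_length = 50,
    stall_force = 6, detach_force = 3, attach_rate = 0.15,
    detach_rate_active = 800 * log(2) / 630,  # 0.880 /s
    detach_rate_inactive = 0.1, back_velocity = 5, step_size = 8,
    frac_inactive = 0.2, frac_diffusive = 0, diffusive_rate = 0,
    schnitzer = default_schnitzer(), polarity = 1L,
    vmax_meanlog = unname(ln["meanlog"]), vmax_sdlog = unname(ln["sdlog"]))
  do.call(motor_params, utils::modifyList(defaults, list(...)))
}

#' Default DDB parameters
#'
#' Literature-plausible constants for the minus-end directed
#' dynein--dynactin--BICD2N (DDB) complex.  `k_d0 = v ln 2 / L_med` from the
#' single-molecule medians (velocity 1460 nm/s, run length 3.29 um); the
#' individual maximal velocity is log-normal matched to the single-molecule
#' median and IQR (1.46 +/- 1.63 um/s).  10% of attaching DDB are inactive
#' and 10% diffuse in the potential of their own spring.
#'
#' @param ... Named overrides for any [motor_params()] field.
#' @return A `motor_params` object.
#' @export
ddb_params <- function(...) {
  ln <- lnorm_from_median_iqr(1460, 1630)
  defaults <- list(
    species_name = "DDB", kappa = 0.2, rest_length = 50,
    stall_force = 4, detach_force = 2, attach_rate = 0.05,
    detach_rate_active = 1460 * log(2) / 3290,  # 0.308 /s
    detach_rate_inactive = 0.1, back_velocity = 5, step_size = 8,
    frac_inactive = 0.1, frac_diffusive = 0.1, diffusive_rate = 50,
    schnitzer = default_schnitzer(), polarity = -1L,
    vmax_meanlog = unname(ln["meanlog"]), vmax_sdlog = unname(ln["sdlog"]))
  do.call(motor_params, utils::modifyList(defaults, list(...)))
}
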