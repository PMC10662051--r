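#' Piecewise-Hookean motor force
#'
#' Force exerted on the cargo by a motor whose head is deflected by `dx`
#' relative to the cargo.  The spring has a dead zone of half-width
#' `rest_length`: no force while `|dx| <= rest_length`, Hookean beyond.
#'
#' @param dx Deflection `head position - cargo position` (nm); vectorised.
#' @param kappa Spring stiffness (pN/nm).
#' @param rest_length Rest length L (nm).
#' @return Signed force (pN), positive towards increasing x.
#' @export
motor_force <- function(dx, kappa, rest_length) {
  stopifnot(kappa >= 0, rest_length >= 0)
  ifelse(dx > rest_length, kappa * (dx - rest_length),
         ifelse(dx < -rest_length, kappa * (dx + rest_length), 0))
}

schnitzer_rate_r <- function(f_res, atp, kcat0, sc, delta, kBT) {
  boltz <- exp(f_res * delta / kBT)
  kcat <- kcat0 / (sc$p_cat + sc$q_cat * boltz)
  if (!is.finite(atp)) return(kcat)
  kb <- sc$k_b0 / (sc$p_b + sc$q_b * boltz)
  kcat * atp / (atp + kcat / kb)
}

#' Force- and ATP-dependent stepping rate
#'
#' Michaelis--Menten stepping rate whose V_max (`k_cat`) and ATP-binding
#' rate (`k_b`) are Boltzmann-distributed in the resisting load with a
#' shared load distance `delta`:
#' `k_m(F) = k_m0 / (p_m + q_m exp(F delta / kBT))`, `m in {cat, b}`, and
#' `s(ATP, F) = k_cat(F) ATP / (ATP + k_cat(F)/k_b(F))`.
#' Three regimes apply, decided by the species polarity:
#' resisting loads below stall use the formula above; assisting loads use
#' the zero-load rate; resisting loads at or above the stall force produce
#' constant slow backward stepping at `back_velocity / step_size`
#' (returned negative).
#'
#' @param force Signed force on the motor-cargo link (pN), positive towards
#'   increasing x; vectorised.
#' @param atp ATP concentration (mM); `Inf` for saturating ATP.
#' @param params A [motor_params()] object.
#' @param vmax Individual maximal (zero-load) velocity (nm/s); defaults to
#'   the species' median.
#' @param delta Calibrated load distance (nm); obtain with
#'   [calibrate_delta()].
#' @param kBT Thermal energy (pN nm).
#' @return Stepping rate (1/s); negative values denote backward stepping
#'   above stall.
#' @export
stepping_rate <- function(force, atp, params, vmax = exp(params$vmax_meanlog),
                          delta = NULL, kBT = 4.11) {
  if (is.null(delta))
    rlang::abort("`delta` is not calibrated; run calibrate_delta() first")
  kcat0 <- vmax / params$step_size
  sc <- params$schnitzer
  vapply(force, function(f) {
    resisting <- params$polarity * f > 0
    f_res <- if (resisting) abs(f) else 0
    if (resisting && f_res > params$stall_force)
      return(-params$back_velocity / params$step_size)
    schnitzer_rate_r(f_res, atp, kcat0, sc, delta, kBT)
  }, numeric(1))
}

#' Calibrate the load distance delta
#'
#' Finds the load distance `delta` such that the stepping rate evaluated at
#' the stall force equals `target` (0.1 /s), by bracketed root finding.
#' `delta` depends on the individual maximal velocity through
#' `k_cat0 = vmax / d`, so it is recalibrated per motor.
#'
#' @inheritParams stepping_rate
#' @param target Stepping rate at stall (1/s).
#' @return Calibrated `delta` (nm) with relative residual below 1e-9.
#' @export
calibrate_delta <- function(params, atp, vmax = exp(params$vmax_meanlog),
                            target = 0.1, kBT = 4.11) {
  kcat0 <- vmax / params$step_size
  sc <- params$schnitzer
  fs <- params$stall_force
  f <- function(delta) schnitzer_rate_r(fs, atp, kcat0, sc, delta, kBT) - target
  if (f(0) <= 0)
    rlang::abort("zero-load stepping rate is at or below the stall target; parameters inconsistent")
  hi <- 1
  while (f(hi) > 0) {
    hi <- hi * 2
    if (hi > 1e6)
      rlang::abort("no sign change found while bracketing delta")
  }
  stats::uniroot(f, c(0, hi), tol = 1e-12)$root
}

#' Bell-type detachment rate
#'
#' Load-dependent unbinding rate `k_d(F) = k_d0 exp(|F| / F_d)`, increasing
#' exponentially with the magnitude of the load.  `literal_sign = TRUE`
#' selects the decreasing variant `k_d0 exp(-|F| / F_d)` (catch-bond-like),
#' provided for comparison.
#'
#' @param force Signed or absolute load (pN); vectorised.
#' @param k_d0 Force-free detachment rate (1/s).
#' @param detach_force Detachment force scale F_d (pN).
#' @param literal_sign Use the decreasing exponent instead.
#' @return Detachment rate (1/s).
#' @export
detachment_rate <- function(force, k_d0, detach_force,
                            literal_sign = FALSE) {
  stopifnot(k_d0 > 0, detach_force > 0)
  s <- if (literal_sign) -1 else 1
  k_d0 * exp(s * abs(force) / detach_force)
}

#' Hopping rates of a diffusive motor
#'
#' A diffusive motor hops on the lattice with rates biased towards its
#' spring equilibrium: `s_toward = s0 exp(+|F| d / 2 kBT)` and
#' `s_away = s0 exp(-|F| d / 2 kBT)`; both equal `s0` when unloaded.  The
#' ratio `s_toward / s_away = exp(|F| d / kBT)` satisfies detailed balance
#' with respect to the spring's Boltzmann distribution.
#'
#' @param force Load on the motor (pN); vectorised.
#' @param s0 Unloaded hopping rate (1/s).
#' @param step_size Lattice step d (nm).
#' @param kBT Thermal energy (pN nm).
#' @return A tibble with columns `toward` and `away` (1/s).
#' @export
diffusive_rates <- function(force, s0, step_size, kBT = 4.11) {
  stopifnot(s0 > 0)
  b <- abs(force) * step_size / (2 * kBT)
  tibble::tibble(toward = s0 * exp(b), away = s0 * exp(-b))
}
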