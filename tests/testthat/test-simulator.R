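test_that("motor counts follow the sigma(mu) Gaussian", {
  expect_true(all(sample_motor_count(0, n = 100) == 0))
  set.seed(11)
  draws <- sample_motor_count(8, n = 1e5)
  se_mean <- 1.0683 * sqrt(8) / sqrt(1e5)
  expect_lt(abs(mean(draws) - 8), 3 * se_mean)
  expect_lt(abs(sd(draws) - 1.0683 * sqrt(8)) / (1.0683 * sqrt(8)), 0.05)
  expect_true(all(draws >= 0))
  expect_error(sample_motor_count(-1), "non-negative")
})

test_that("species split is binomial in the mean ratio", {
  expect_equal(split_species(0, 8, 14), c(n_ddb = 0L, n_kif = 0L))
  set.seed(12)
  expect_true(all(replicate(50, split_species(7, 8, 0)[["n_ddb"]]) == 7))
  nd <- replicate(2e4, split_species(22, 8, 14)[["n_ddb"]])
  se <- sqrt(22 * (8 / 22) * (14 / 22)) / sqrt(2e4)
  expect_lt(abs(mean(nd) - 8), 3 * se)
  expect_error(split_species(5, 0, 0), "zero")
})

test_that("activity classes are drawn with the stated fractions", {
  set.seed(13)
  kcls <- assign_activity(kif16b_params(), n = 1e5)
  expect_lt(abs(mean(kcls == "inactive") - 0.20), 3 * sqrt(0.2 * 0.8 / 1e5))
  expect_equal(sum(kcls == "diffusive"), 0)
  dcls <- assign_activity(ddb_params(), n = 1e5)
  expect_lt(abs(mean(dcls == "diffusive") - 0.10), 3 * sqrt(0.1 * 0.9 / 1e5))
  expect_lt(abs(mean(dcls == "inactive") - 0.10), 3 * sqrt(0.1 * 0.9 / 1e5))
  p0 <- kif16b_params(frac_inactive = 0)
  expect_true(all(assign_activity(p0, n = 500) == "active"))
})

test_that("lane choice is a truncated discrete Gaussian", {
  set.seed(14)
  lanes <- sample_lane(1e5)
  expect_true(all(lanes >= -3 & lanes <= 3))
  tab <- table(factor(lanes, levels = -3:3))
  expect_equal(unname(which.max(tab)), 4L)  # mode at lane 0
  ratio <- tab[["0"]] / tab[["1"]]
  expect_lt(abs(ratio - exp(0.5)), 0.08)    # density ratio exp(1/2)
})

test_that("cargo force sums absolute motor forces", {
  expect_equal(cargo_force(numeric(0), 0, 0.2, 50), 0)
  # heads at +/-60 nm: one pulls +2 pN, the other -2 pN, cargo force 4 pN
  expect_equal(cargo_force(c(60, -60), 0, 0.2, 50), 4)
  expect_equal(cargo_force(30, 0, 0.2, 50), 0)  # inside dead zone
})

test_that("cargo relaxation finds the spring energy minimum", {
  # one motor, cargo 50 nm beyond the rest length: relaxes into the
  # zero-force interval (tolerance 2 proposal steps)
  r <- relax_cargo(head_pos = 0, kappa = 0.3, rest_length = 50, x0 = -100,
                   kBT = 0, n_proposals = 100, step_size = 2)
  expect_lt(abs(r$x), 50 + 2 * 2)
  expect_lte(r$energy_final, r$energy_initial + 1e-9)
  expect_equal(r$force, 0)
  # two opposing motors with symmetric deflections: mean relaxed position
  # sits at the midpoint
  set.seed(15)
  xs <- replicate(300, relax_cargo(c(-100, 100), 0.3, 50, x0 = 37,
                                   kBT = 4.11)$x)
  expect_lt(abs(mean(xs)), 2)
  # kBT -> 0: pure descent, energy never increases
  r0 <- relax_cargo(c(-100, 100), 0.3, 50, x0 = 90, kBT = 0)
  expect_lte(r0$energy_final, r0$energy_initial + 1e-12)
  # no attached motors: position unchanged
  expect_equal(relax_cargo(numeric(0), 0.3, 50, x0 = 12)$x, 12)
})

test_that("identical config and seed give bit-identical tracks", {
  cfg <- sim_config(mean_n_ddb = 2, mean_n_kif = 3, max_time = 12,
                    relax_time = 1)
  a <- simulate_cargoes(3, cfg, seed = 77)
  b <- simulate_cargoes(3, cfg, seed = 77)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "runs"), attr(b, "runs"))
})

test_that("zero motors terminate the simulation immediately", {
  cfg <- sim_config(fixed_counts = c(0L, 0L), max_time = 10)
  out <- simulate_cargo(cfg)
  expect_equal(out$status, "no_events")
  expect_equal(nrow(out$runs), 0)
})

test_that("exclusion holds in crowded conditions (engine assertion)", {
  cfg <- sim_config(fixed_counts = c(5L, 10L), max_time = 10,
                    relax_time = 1, validate = TRUE)
  ddb <- ddb_params(attach_rate = 0.05 * 32)
  kif <- kif16b_params(attach_rate = 0.15 * 32)
  set.seed(16)
  expect_no_error(simulate_cargo(cfg, ddb, kif))
})

test_that("single-motor run lengths are exponential with mean v/k_d0", {
  su <- single_motor_setup("kif", vmax = 800)
  tracks <- simulate_cargoes(2000, su$cfg, su$ddb, su$kif, seed = 17)
  runs <- attr(tracks, "runs")
  len <- abs(runs$x_detach - runs$x_attach)
  m_exp <- 800 / su$kif$detach_rate_active
  expect_lt(abs(mean(len) - m_exp), 3 * m_exp / sqrt(length(len)))
  # exponential shape (lattice-discretised)
  expect_lt(suppressWarnings(
    stats::ks.test(len, "pexp", 1 / m_exp)$statistic), 0.05)
  # net displacement carries the species polarity
  expect_true(all(runs$x_detach >= runs$x_attach))
})

test_that("waiting times and event selection follow Gillespie rates", {
  # one DDB (k_a = 1/s) and one KIF16B (k_a = 3/s): the first attachment
  # is KIF16B with probability 3/4, after Exp(4) waiting time
  cfg <- sim_config(fixed_counts = c(1L, 1L), relax_time = 0, max_time = 6,
                    metropolis_n = 0)
  ddb <- ddb_params(attach_rate = 1, detach_rate_active = 12,
                    frac_inactive = 0, frac_diffusive = 0, vmax_fixed = 10)
  kif <- kif16b_params(attach_rate = 3, detach_rate_active = 12,
                       frac_inactive = 0, vmax_fixed = 10)
  set.seed(18)
  firsts <- purrr::map_dfr(seq_len(400), function(i) {
    out <- simulate_cargo(cfg, ddb, kif)
    r <- out$runs[order(out$runs$t_attach), ]
    r[1, c("species", "t_attach")]
  })
  expect_lt(abs(mean(firsts$species == "KIF16B") - 0.75),
            3 * sqrt(0.75 * 0.25 / 400))
  expect_lt(abs(mean(firsts$t_attach) - 0.25), 3 * 0.25 / sqrt(400))
})

test_that("raising the attachment rate raises the attached motor number", {
  mean_att <- function(ka_scale, seed) {
    cfg <- sim_config(fixed_counts = c(0L, 5L), relax_time = 0,
                      max_time = 30)
    kif <- kif16b_params(attach_rate = 0.15 * ka_scale)
    tr <- simulate_cargoes(10, cfg, kif16b = kif, seed = seed)
    mean(tr$n_att_kif)
  }
  expect_gt(mean_att(10, seed = 19), mean_att(1, seed = 19))
})

test_that("a lone diffusive motor samples the Boltzmann distribution", {
  # birth-death oracle: stationary weights from the chain's own rates
  kappa <- 0.2; L <- 16; d <- 8; kBT <- 4.11; s0 <- 20
  set.seed(20)
  ch <- cargotug:::cpp_diffusive_chain(2e5, s0, d, kappa, L, kBT, 0, 0L)
  occ <- tapply(ch$dwell, factor(ch$site, levels = -8:8), sum)
  occ[is.na(occ)] <- 0
  occ <- occ / sum(occ)
  # enumerate detailed balance: pi_{j+1}/pi_j = r_plus(j)/r_minus(j+1)
  rates <- function(j) {
    dx <- j * d
    f <- abs(motor_force(dx, kappa, L))
    if (dx > L) c(plus = s0 * exp(-f * d / (2 * kBT)),
                  minus = s0 * exp(f * d / (2 * kBT)))
    else if (dx < -L) c(plus = s0 * exp(f * d / (2 * kBT)),
                        minus = s0 * exp(-f * d / (2 * kBT)))
    else c(plus = s0, minus = s0)
  }
  lpi <- cumsum(c(0, vapply(-8:7, function(j)
    log(rates(j)[["plus"]] / rates(j + 1)[["minus"]]), numeric(1))))
  pi_th <- exp(lpi - max(lpi)); pi_th <- pi_th / sum(pi_th)
  expect_lt(sum(abs(occ - pi_th)) / 2, 0.05)  # total variation
})

test_that("single-species cargoes move with the species polarity", {
  su_k <- single_motor_setup("kif", vmax = 800, max_time = 30)
  tr <- simulate_cargoes(20, su_k$cfg, su_k$ddb, su_k$kif, seed = 21)
  disp <- tapply(tr$x_nm, tr$track_id, function(x) x[length(x)] - x[1])
  expect_true(all(disp >= 0))
  su_d <- single_motor_setup("ddb", vmax = 1460, max_time = 30)
  trd <- simulate_cargoes(20, su_d$cfg, su_d$ddb, su_d$kif, seed = 22)
  dispd <- tapply(trd$x_nm, trd$track_id, function(x) x[length(x)] - x[1])
  expect_true(all(dispd <= 0))
})
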