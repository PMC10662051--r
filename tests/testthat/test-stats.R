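test_that("instantaneous velocities are frame-to-frame displacements", {
  tr <- tibble::tibble(t_s = seq(0, 1, 0.1), x_nm = rep(5, 11))
  expect_equal(instantaneous_velocities(tr), rep(0, 10))
  tr2 <- tibble::tibble(t_s = seq(0, 1, 0.1), x_nm = 700 * seq(0, 1, 0.1))
  expect_equal(instantaneous_velocities(tr2), rep(700, 10))
  # telescoping: the mean equals net displacement over total time
  set.seed(40)
  tr3 <- tibble::tibble(t_s = seq(0, 2, 0.1), x_nm = cumsum(rnorm(21, 0, 30)))
  expect_equal(mean(instantaneous_velocities(tr3)),
               (tr3$x_nm[21] - tr3$x_nm[1]) / (tr3$t_s[21] - tr3$t_s[1]))
})

test_that("run mean velocity averages in-segment instantaneous velocities", {
  tr <- linear_track(v = 600, duration = 3, noise_sd = 0)
  seg <- tibble::tibble(i_start = 5L, i_end = 20L)
  expect_equal(run_mean_velocity(tr, seg), 600)
  set.seed(41)
  trn <- linear_track(v = 600, duration = 3, noise_sd = 15)
  expect_equal(run_mean_velocity(trn, seg),
               mean(diff(trn$x_nm[5:20]) / 0.1))
  # a two-frame run reduces to a single instantaneous velocity
  expect_equal(run_mean_velocity(trn, tibble::tibble(i_start = 1L, i_end = 2L)),
               (trn$x_nm[2] - trn$x_nm[1]) / 0.1)
})

test_that("track classification follows the run-composition rules", {
  c1 <- classify_track(segments_from_kinds(c("run_neg", "pause", "run_neg")))
  expect_equal(as.character(c1$label), "minus")
  expect_equal(c1$n_nonreversal_pauses, 1L)
  expect_equal(c1$n_reversal_pauses, 0L)
  c2 <- classify_track(segments_from_kinds(c("run_neg", "pause", "run_pos")))
  expect_equal(as.character(c2$label), "reversal")
  expect_equal(c2$n_reversal_pauses, 1L)
  c3 <- classify_track(segments_from_kinds("pause"))
  expect_equal(as.character(c3$label), "stationary")
  # instantaneous reversal: opposite runs with no pause in between
  c4 <- classify_track(segments_from_kinds(c("run_pos", "run_neg")))
  expect_equal(as.character(c4$label), "reversal")
  expect_equal(c4$n_instant_reversals, 1L)
  expect_error(classify_track(segments_from_kinds(character(0))), "empty")
})

test_that("classification is exhaustive, exclusive and conserves reversals", {
  set.seed(42)
  kinds <- c("run_pos", "run_neg", "pause")
  for (rep in 1:50) {
    ks <- sample(kinds, sample(1:8, 1), replace = TRUE)
    # avoid back-to-back pauses so each sign change maps to one event
    ks <- ks[c(TRUE, ks[-1] != "pause" | ks[-length(ks)] != "pause")]
    cl <- classify_track(segments_from_kinds(ks))
    expect_false(is.na(cl$label))   # exactly one of the four labels
    runs <- ks[ks != "pause"]
    sign_changes <- if (length(runs) > 1) sum(runs[-1] != runs[-length(runs)])
      else 0L
    expect_equal(cl$n_reversal_pauses + cl$n_instant_reversals,
                 sign_changes)
    expect_equal(cl$n_reversal_pauses + cl$n_nonreversal_pauses,
                 cl$n_pauses)
  }
})

test_that("uniform weights reduce weighted estimators to classical ones", {
  set.seed(43)
  x <- rnorm(40, 2, 1.5)
  m <- weighted_moments(x)
  expect_equal(m[["mean"]], mean(x), tolerance = 1e-9)
  expect_equal(m[["sd"]], sd(x) * sqrt((40 - 1) / 40) * sqrt(40 / (40 - 1)),
               tolerance = 1e-9)
  expect_equal(m[["sd"]], sd(x), tolerance = 1e-9)
  expect_equal(m[["sem"]], sd(x) / sqrt(39), tolerance = 1e-9)
  # weighted ECDF with uniform weights equals stats::ecdf
  Fw <- weighted_ecdf(x)
  Fu <- stats::ecdf(x)
  grid <- seq(min(x) - 1, max(x) + 1, length.out = 200)
  expect_equal(Fw(grid), Fu(grid), tolerance = 1e-9)
  # KS statistic and p equal the classical asymptotic two-sample test
  y <- rnorm(35, 2.6, 1.2)
  ours <- weighted_ks_test(x, y)
  ref <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  expect_equal(unname(ours$statistic), unname(ref$statistic),
               tolerance = 1e-9)
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-7)
})

test_that("weighted estimators match brute-force evaluation", {
  set.seed(44)
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    x <- rnorm(n); w <- runif(n); wn <- w / sum(w)
    m <- weighted_moments(x, w)
    mu <- sum(wn * x)
    expect_equal(m[["mean"]], mu, tolerance = 1e-12)
    sd_bf <- sqrt(sum(wn * (x - mu)^2) / ((n - 1) / n))
    expect_equal(m[["sd"]], sd_bf, tolerance = 1e-12)
    expect_equal(m[["sem"]], sd_bf / sqrt(n - 1), tolerance = 1e-12)
  }
  # weighted KS statistic equals the sup over a fine grid of ECDF gaps
  x <- rnorm(25); wx <- runif(25)
  y <- rnorm(20, 0.8); wy <- runif(20)
  ks <- weighted_ks_test(x, y, wx, wy)
  Fa <- weighted_ecdf(x, wx); Fb <- weighted_ecdf(y, wy)
  grid <- sort(c(x, y))
  expect_equal(unname(ks$statistic), max(abs(Fa(grid) - Fb(grid))),
               tolerance = 1e-12)
})

test_that("weighted KS handles degenerate and extreme cases", {
  x <- c(1, 2, 3)
  expect_equal(unname(weighted_ks_test(x, x)$statistic), 0)
  expect_equal(unname(weighted_ks_test(1:5, 11:15)$statistic), 1)
  expect_error(weighted_ks_test(numeric(0), 1:3), "empty")
})

test_that("Bonferroni multiplies and caps p-values", {
  expect_equal(bonferroni(0.01, 3), 0.03)
  expect_equal(bonferroni(0.6, 3), 1)
  expect_equal(bonferroni(c(0.2, 0.5), 1), c(0.2, 0.5))
})

test_that("spatial pause frequency is distance-weighted with printed SD/SEM", {
  # single track: 2 pauses over 4 um; SEM undefined at N = 1, returned 0
  expect_warning(pf1 <- spatial_pause_frequency(
    tibble::tibble(n_pauses = 2, distance = 4)), "single")
  expect_equal(pf1$weighted_mean, 0.5)
  expect_equal(pf1$weighted_sem, 0)
  # equal distances reduce to the unweighted mean of x_f
  tp <- tibble::tibble(n_pauses = c(1, 2, 4), distance = c(5, 5, 5))
  expect_equal(spatial_pause_frequency(tp)$weighted_mean,
               mean(tp$n_pauses / tp$distance))
  # brute-force check of the printed formulas on a random fixture
  set.seed(45)
  tp2 <- tibble::tibble(n_pauses = rpois(12, 3), distance = runif(12, 1, 9))
  pf <- spatial_pause_frequency(tp2)
  w <- tp2$distance / sum(tp2$distance)
  xf <- tp2$n_pauses / tp2$distance
  xbar <- sum(w * xf)
  sdf <- sqrt(sum(w * (xf - xbar)^2) / ((12 - 1) / 12))
  expect_equal(pf$weighted_mean, xbar)
  expect_equal(pf$weighted_sd, sdf)
  expect_equal(pf$weighted_sem, sdf / sqrt(11))
  # zero-distance tracks are excluded with a warning
  expect_warning(spatial_pause_frequency(
    tibble::tibble(n_pauses = c(1, 1, 2), distance = c(0, 3, 5))),
    "zero distance")
})

test_that("resampling chops tracks to the target duration distribution", {
  tr <- linear_track(v = 100, duration = 12)
  # target equal to the track duration gives exactly one piece
  p1 <- resample_to_durations(tr, 12)
  expect_equal(length(unique(p1$piece_id)), 1L)
  expect_equal(p1$weight[1], 1)
  # conservation: total piece time never exceeds simulated time
  set.seed(46)
  tracks <- dplyr::bind_rows(lapply(1:40, function(i)
    linear_track(v = 50, duration = 60, track_id = i)))
  target <- make_duration_sample(8, 6, 400, seed = 1)
  pieces <- resample_to_durations(tracks, target, seed = 2)
  tot <- sum(tapply(pieces$t_s, pieces$piece_id, max))
  expect_lte(tot, 40 * 60)
  expect_equal(sum(tapply(pieces$weight, pieces$piece_id, unique)), 1)
  # piece durations reproduce the target distribution
  pd <- tapply(pieces$piece_duration_s, pieces$piece_id, unique)
  expect_lt(suppressWarnings(stats::ks.test(pd, target)$statistic), 0.1)
})

test_that("elongation index measures shape anisotropy", {
  expect_equal(elongation_index(100, 100), 0)
  expect_equal(elongation_index(300, 100), 0.5)
  long <- seq(100, 500, by = 50)
  expect_true(all(diff(elongation_index(long, 100)) > 0))
  expect_error(elongation_index(50, 100), "long >= short")
})

test_that("tidy and glance methods expose fit summaries", {
  tr <- make_track(rpr_blueprint(), seed = 3)$track
  set.seed(47)
  fit <- anneal_track(tr)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("t_s", "x_nm", "slope_to_next"))
  gl <- glance(fit)
  expect_equal(gl$n_cp, fit$n_cp)
  ks <- weighted_ks_test(rnorm(10), rnorm(10))
  expect_named(tidy(ks), c("statistic", "p.value", "n_eff1", "n_eff2",
                           "method", "alternative"))
})

test_that("segmented tracks plot as coloured position-time traces", {
  tr <- make_track(rpr_blueprint(), seed = 4)$track
  seg <- segment_track(tr, seed = 9)
  p <- ggplot2::autoplot(seg)
  expect_s3_class(p, "ggplot")
  cf <- class_fractions(classify_tracks(seg))
  expect_s3_class(plot_class_fractions(cf), "ggplot")
})
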