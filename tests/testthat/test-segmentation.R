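test_that("piecewise-linear evaluation interpolates the change points", {
  cp_t <- c(0, 2, 5); cp_x <- c(0, 100, -50)
  expect_equal(eval_piecewise(cp_t, cp_x, c(0, 2, 5)), c(0, 100, -50))
  expect_equal(eval_piecewise(c(0, 10), c(0, 80), 5), 40)  # midpoint
  # collinear change points reproduce the straight line
  tq <- seq(0, 6, by = 0.3)
  expect_equal(eval_piecewise(c(0, 2, 6), c(1, 7, 19), tq), 1 + 3 * tq)
  expect_error(eval_piecewise(cp_t, cp_x, 6), "outside")
})

test_that("cost is residual sum plus mu per interior change point", {
  tr <- linear_track(v = 300, duration = 8, noise_sd = 0)
  ends <- range(tr$t_s)
  expect_equal(segment_cost(tr, ends, 300 * ends, 10000), 0)
  # one interior change point exactly on the line costs mu = 10,000
  expect_equal(segment_cost(tr, c(0, 4, 8), 300 * c(0, 4, 8), 10000), 10000)
  # noisy track: matches an independently computed residual sum
  set.seed(30)
  tr2 <- linear_track(v = 300, duration = 8, noise_sd = 25)
  cp_t <- c(0, 3.05, 8); cp_x <- c(10, 900, 2300)
  f <- approx(cp_t, cp_x, xout = tr2$t_s)$y
  expect_equal(segment_cost(tr2, cp_t, cp_x, 10000),
               sum((tr2$x_nm - f)^2) + 10000)
})

test_that("proposal moves have the configured frequencies and limits", {
  set.seed(31)
  tr <- linear_track(v = 200, duration = 10, noise_sd = 10)
  cp_t <- c(0, 3, 7, 10); cp_x <- c(0, 600, 1400, 2000)
  cfg <- anneal_config(move_probs = c(shift = 0.5, add = 0.3, remove = 0.2))
  moves <- replicate(4000, propose_change_points(tr, cp_t, cp_x, cfg)$move)
  freq <- table(moves) / 4000
  expect_lt(abs(freq[["shift"]] - 0.5), 3 * sqrt(0.5 * 0.5 / 4000))
  expect_lt(abs(freq[["add"]] - 0.3), 3 * sqrt(0.3 * 0.7 / 4000))
  # zero-amplitude shift proposes the identical configuration
  cfg0 <- anneal_config(eps_x = 0, eps_t = 0,
                        move_probs = c(shift = 1, add = 0, remove = 0))
  pr <- propose_change_points(tr, cp_t, cp_x, cfg0)
  expect_equal(pr$cp_t, cp_t)
  expect_equal(pr$cp_x, cp_x)
  # add then remove recovers the original configuration
  cfg_add <- anneal_config(move_probs = c(shift = 0, add = 1, remove = 0))
  pr2 <- propose_change_points(tr, cp_t, cp_x, cfg_add)
  if (!pr2$rejected) {
    k <- setdiff(seq_along(pr2$cp_t), match(cp_t, pr2$cp_t))
    expect_equal(pr2$cp_t[-k], cp_t)
  }
  # removal with no interior points is a counted no-op
  pr3 <- propose_change_points(tr, c(0, 10), c(0, 2000),
    anneal_config(move_probs = c(shift = 0, add = 0, remove = 1)))
  expect_true(pr3$rejected)
})

test_that("annealing drops needless change points on a straight track", {
  set.seed(32)
  tr <- linear_track(v = 400, duration = 10, noise_sd = 0)
  fit <- anneal_track(tr)
  expect_equal(fit$n_cp, 0L)      # H = 0 beats any cp by mu
  expect_lt(fit$H, 1e-9)
})

test_that("annealing recovers a single kink and is seed-deterministic", {
  hits <- vapply(1:20, function(s) {
    set.seed(100 + s)
    bp <- track_blueprint(c(0, 5), c(0, 800), 10, noise_sd = 0)
    tr <- make_track(bp)$track
    fit <- anneal_track(tr)
    fit$n_cp == 1 && abs(fit$cp$t_s[2] - 5) <= 0.2
  }, logical(1))
  expect_gte(sum(hits), 19)
  set.seed(33)
  tr <- make_track(rpr_blueprint(), seed = 1)$track
  f1 <- segment_track(tr, seed = 5)
  f2 <- segment_track(tr, seed = 5)
  expect_identical(attr(f1, "changepoints")$cp, attr(f2, "changepoints")$cp)
})

test_that("annealing improves on the initial configuration", {
  improved <- vapply(1:20, function(s) {
    tr <- make_track(rpr_blueprint(v1 = stats::runif(1, 500, 1200),
                                   v2 = -stats::runif(1, 500, 1200)),
                     seed = 200 + s)$track
    set.seed(300 + s)
    fit <- anneal_track(tr)
    # reconstruct the equally spaced initial configuration
    n0 <- max(1, floor(diff(range(tr$t_s)) / 5))
    t0 <- seq(min(tr$t_s), max(tr$t_s), length.out = n0 + 2)
    x0 <- approx(tr$t_s, tr$x_nm, xout = t0)$y
    h0 <- segment_cost(tr, t0, x0, 10000)
    fit$H <= h0
  }, logical(1))
  expect_gte(sum(improved), 19)
})

test_that("incremental cost bookkeeping matches full recomputation", {
  tr <- make_track(rpr_blueprint(), seed = 7)$track
  set.seed(34)
  fit <- anneal_track(tr, anneal_config(check_every = 50))
  expect_lt(fit$max_incremental_rel_err, 1e-6)
})

test_that("post-processing applies the slope, one-point and distance rules", {
  # three segments: slow drift (pause), fast-but-short (pause), fast run
  bp <- track_blueprint(c(0, 4, 4.4), c(50, 800, -800), 8, noise_sd = 0)
  mk <- make_track(bp)
  segs <- postprocess_segments(mk$track, c(0, 4, 4.4, 8))
  expect_equal(segs$kind, c("pause", "pause", "run_neg"))
  # +50 nm/s slope -> pause; 800 nm/s over 0.4 s = 320 nm -> pause;
  # -800 nm/s over 3.6 s = -2880 nm -> negative run
  expect_equal(segs$slope_nm_s[1], 50, tolerance = 1e-6)
  expect_lt(abs(segs$distance_nm[2]) , 500)
  # segments tile the sample index range exactly
  expect_equal(segs$i_start[1], 1L)
  expect_equal(segs$i_end[nrow(segs)], nrow(mk$track))
  expect_true(all(segs$i_start[-1] == segs$i_end[-nrow(segs)] + 1L))
  # a one-point segment is merged into the following segment
  tr <- linear_track(v = 1000, duration = 2, noise_sd = 0)
  segs1 <- postprocess_segments(tr, c(0, 0.05, 2))  # first piece: 1 sample
  expect_equal(nrow(segs1), 1L)
  expect_equal(segs1$i_start, 1L)
  expect_equal(segs1$i_end, nrow(tr))
})

test_that("same-kind merging is available but off by default", {
  tr <- linear_track(v = 1000, duration = 6, noise_sd = 0)
  cps <- c(0, 2, 4, 6)
  default <- postprocess_segments(tr, cps)
  expect_equal(nrow(default), 3L)
  merged <- postprocess_segments(tr, cps, anneal_config(merge_same_kind = TRUE))
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$kind, "run_pos")
})
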