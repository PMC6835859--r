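test_that("temporal filters implement the exact first-order recursions", {
  x <- c(0, 1, 1, 1, 0.5, 0, 0, 2)
  dt <- 0.001; tau <- 0.013
  a <- exp(-dt / tau)
  y <- numeric(8); y[1] <- a * x[1] + (1 - a) * x[1]
  for (t in 2:8) y[t] <- a * y[t - 1] + (1 - a) * x[t]
  got <- apparentmotion:::lp_filter(matrix(x), tau, dt)
  expect_equal(drop(got), y, tolerance = 1e-12)
  # high pass kills DC: long constant input decays to zero
  hp <- apparentmotion:::hp_filter(matrix(rep(3, 3000)), 0.04, dt)
  expect_equal(hp[1], 0)
  expect_lt(abs(hp[3000]), 1e-12)
})

test_that("a uniform stimulus evokes no detector response", {
  stim <- spacetime_stimulus(matrix(27.1, 400, 300), 0.05, 0.001)
  out <- rd_output(stim, normalized_class(1), 10)
  expect_equal(max(abs(out$response)), 0, tolerance = 1e-12)
})

test_that("normalisation yields unit response at the optimum and nowhere above", {
  cls <- normalized_class(1)
  tm <- rd_temporal_filters()
  opt <- rd_grating_response(cls, tm, attr(cls, "opt_fs_cpd"),
                             attr(cls, "opt_ft_hz"))
  expect_equal(opt, 1, tolerance = 1e-6)
  # sampled off-optimum gratings stay at or below 1
  probe <- expand.grid(fs = c(0.03, 0.1, 0.3), ft = c(2, 7, 20))
  vals <- mapply(function(a, b) rd_grating_response(cls, tm, a, b),
                 probe$fs, probe$ft)
  expect_true(all(vals <= 1 + 0.01))
  # opposite drift gives the mirrored response
  expect_equal(rd_grating_response(cls, tm, attr(cls, "opt_fs_cpd"),
                                   -attr(cls, "opt_ft_hz")),
               -1, tolerance = 1e-6)
})

test_that("the coarse class is tuned to lower spatial frequencies", {
  expect_lt(attr(normalized_class(2), "opt_fs_cpd"),
            attr(normalized_class(1), "opt_fs_cpd"))
})

test_that("the correlator is quadratic in stimulus contrast", {
  raw <- rd_class(1.07, 1.0)
  tm <- rd_temporal_filters()
  r1 <- rd_grating_response(raw, tm, 0.1, 6, amplitude_cdm2 = 10)
  r2 <- rd_grating_response(raw, tm, 0.1, 6, amplitude_cdm2 = 20)
  expect_equal(r2 / r1, 4, tolerance = 0.02)
})

test_that("votes threshold the trailing average", {
  thr <- 0.02
  expect_equal(unique(detector_vote(rep(2 * thr, 500), thr)), 1L)
  expect_equal(unique(detector_vote(rep(0, 500), thr)), 0L)
  expect_equal(unique(detector_vote(rep(-2 * thr, 500), thr)), -1L)
  # zero-mean oscillation much faster than the window is averaged away
  fast <- 5 * thr * sin(2 * pi * 100 * (1:1000) / 1000)
  votes <- detector_vote(fast, thr)
  expect_equal(mean(votes[400:1000] == 0), 1)
  # expanding start-up window
  expect_warning(detector_vote(rep(0.1, 100), thr, window_s = 0.3), "window")
})

test_that("the trailing boxcar matches a hand-rolled running mean", {
  x <- matrix(rnorm(40), 20, 2)
  got <- apparentmotion:::boxcar_mean(x, 5L)
  manual <- sapply(1:2, function(j) {
    vapply(1:20, function(t) mean(x[max(1, t - 4):t, j]), numeric(1))
  })
  expect_equal(got, manual, tolerance = 1e-12)
})

test_that("detector output is antisymmetric under spatial mirroring", {
  sp <- chequerboard_spec(2, 1, seed = 31, duration_s = 0.5)
  geom <- screen_geometry()
  stim <- generate_stimulus(sp, geom, dx_deg = 0.05)
  x0 <- stim$extent_deg / 2
  out <- rd_output(stim, normalized_class(1), x0)
  mirrored <- stim
  mirrored$luminance <- stim$luminance[rev(seq_len(nrow(stim$luminance))), ]
  out_m <- rd_output(mirrored, normalized_class(1), x0)
  expect_equal(out$response, -out_m$response, tolerance = 1e-6)
})

test_that("detector placement respects the retina bounds", {
  stim <- spacetime_stimulus(matrix(27, 100, 10), 0.05, 1 / 85)
  expect_error(rd_output(stim, normalized_class(1), 0.5), "placement")
  cls_big <- rd_class(30, 2)
  expect_error(rd_engine(rd_config(classes = list(cls_big),
                                   retina_extent_deg = 60)),
               "placement")
})

test_that("population response is reproducible and symmetric without signal", {
  cfg <- small_cfg()
  stim <- spacetime_stimulus(matrix(27.1, 1200, 52), 0.05, 1 / 85)
  a <- rd_population_response(stim, cfg, noise_seed = 3)
  b <- rd_population_response(stim, cfg, noise_seed = 3)
  expect_identical(a$r, b$r)
  expect_true(all(a$votes == 0))
  # with satlin the noise-only signal is far inside the dead zone
  expect_lt(max(abs(a$r)), 0.2)
  expect_lt(abs(mean(a$r)), 0.02)
})

test_that("easy conditions are judged in the stimulus direction", {
  cfg <- small_cfg()
  engine <- apparentmotion:::rd_engine(cfg)
  resp <- vapply(1:8, function(k) {
    sp <- chequerboard_spec(4, 2, direction = 1L, seed = 100 + k)
    rd_simulate_trial(sp, cfg, seed = 200 + k, engine = engine)
  }, character(1))
  expect_gte(sum(resp == "right"), 7)
  # and a uniform field yields no judgement
  sp_flat <- chequerboard_spec(4, 2, seed = 1,
                               luminance_dark_cdm2 = 27.0999,
                               luminance_light_cdm2 = 27.1001)
  expect_equal(rd_simulate_trial(sp_flat, cfg, seed = 5, engine = engine),
               "other")
})

test_that("detection degrades as the step size grows", {
  cfg <- small_cfg()
  trials <- rd_simulate_experiment(2, list(c(2, 14)), 12, cfg, seed = 6)
  summ <- condition_summary(trials)
  expect_gt(summ$n_detected[1], summ$n_detected[2])
})

test_that("experiments are balanced, deterministic, and schema-compatible", {
  cfg <- small_cfg()
  a <- rd_simulate_experiment(c(1, 4), c(2, 5), 6, cfg, seed = 11)
  b <- rd_simulate_experiment(c(1, 4), c(2, 5), 6, cfg, seed = 11)
  expect_identical(a, b)
  expect_equal(nrow(a), 2 * 2 * 6)
  counts <- table(a$element_size_deg, a$direction)
  expect_true(all(counts == 6))
  expect_true(all(a$response %in% c("left", "right", "other")))
  path <- tempfile(fileext = ".csv")
  write_trials(a, path)
  expect_equal(nrow(read_trials(path)), nrow(a))
})

test_that("scaling gains and vote thresholds together leaves judgements unchanged", {
  cfg1 <- small_cfg()
  cfg2 <- small_cfg()
  for (i in seq_along(cfg2$classes)) {
    cfg2$classes[[i]]$gain <- cfg2$classes[[i]]$gain * 3
    cfg2$classes[[i]]$vote_threshold <- cfg2$classes[[i]]$vote_threshold * 3
  }
  t1 <- rd_simulate_experiment(2, c(3, 8), 8, cfg1, seed = 21)
  t2 <- rd_simulate_experiment(2, c(3, 8), 8, cfg2, seed = 21)
  expect_identical(t1$response, t2$response)
})

test_that("direction antisymmetry holds end to end under matched seeds", {
  cfg <- small_cfg()
  engine <- apparentmotion:::rd_engine(cfg)
  flip <- c(left = "right", right = "left", other = "other")
  agree <- 0
  for (k in 1:6) {
    sp_r <- chequerboard_spec(2, 2, direction = 1L, seed = 50 + k)
    sp_l <- chequerboard_spec(2, 2, direction = -1L, seed = 50 + k)
    r_r <- rd_simulate_trial(sp_r, cfg, seed = 70 + k, engine = engine)
    r_l <- rd_simulate_trial(sp_l, cfg, seed = 70 + k, engine = engine)
    # same pattern and noise stream, reversed motion: judgements mirror up
    # to pattern-specific fluctuations near the decision boundary
    agree <- agree + (r_l == unname(flip[r_r]))
  }
  expect_gte(agree, 5)
})
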