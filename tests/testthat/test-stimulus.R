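geom <- screen_geometry()

test_that("seeded stimulus generation is reproducible and binary", {
  sp <- chequerboard_spec(2, 1, seed = 42)
  a <- generate_stimulus(sp, geom)
  b <- generate_stimulus(sp, geom)
  expect_identical(a$luminance, b$luminance)
  expect_setequal(unique(as.vector(a$luminance)),
                  c(sp$luminance_dark_cdm2, sp$luminance_light_cdm2))
  expect_equal(a$extent_deg, nrow(a$luminance) * a$dx_deg)
})

test_that("light and dark chequers are equally likely", {
  # pool elements over many seeded patterns: >= 1e4 Bernoulli draws
  light <- unlist(lapply(1:20, function(s) {
    sp <- chequerboard_spec(0.24, 1, seed = s)
    pat <- apparentmotion:::chequer_pattern(sp, 2836, 0.05)
    # one value per element, not per sample
    idx <- !duplicated(floor(((seq_len(2836) - 0.5) * 0.05) / 0.24))
    pat[idx] == sp$luminance_light_cdm2
  }))
  expect_gt(length(light), 1e4)
  expect_gt(binom.test(sum(light), length(light), 0.5)$p.value, 0.001)
})

test_that("frames shift by the step size in the stimulus direction", {
  # cross-correlation oracle: lag of max correlation between consecutive
  # distinct frames equals step/dx in the direction of motion
  for (dir in c(1L, -1L)) {
    sp <- chequerboard_spec(4, 2, direction = dir, seed = 9)
    st <- generate_stimulus(sp, geom)
    cols <- unique(t(st$luminance))
    f1 <- cols[1, ] - mean(cols[1, ])
    f2 <- cols[2, ] - mean(cols[2, ])
    lags <- -80:80
    cc <- vapply(lags, function(l) {
      n <- length(f1)
      idx <- ((seq_len(n) - 1 - l) %% n) + 1
      sum(f1[idx] * f2)
    }, numeric(1))
    expect_equal(lags[which.max(cc)], dir * round(2 / st$dx_deg))
  }
})

test_that("mirroring space is equivalent to negating the direction", {
  sp_r <- chequerboard_spec(4, 2, direction = 1L, seed = 11)
  st_r <- generate_stimulus(sp_r, geom)
  mirrored <- st_r$luminance[rev(seq_len(nrow(st_r$luminance))), ]
  # mirrored rightward stimulus steps leftward: frame-to-frame lag flips
  f1 <- mirrored[, 1] - mean(mirrored[, 1])
  ncols <- unique(t(mirrored))
  f2 <- ncols[2, ] - mean(ncols[2, ])
  lags <- -60:60
  cc <- vapply(lags, function(l) {
    n <- length(f1)
    idx <- ((seq_len(n) - 1 - l) %% n) + 1
    sum(f1[idx] * f2)
  }, numeric(1))
  expect_equal(lags[which.max(cc)], -round(2 / st_r$dx_deg))
})

test_that("displacement events are quantised to dt = step/speed", {
  for (step in c(0.5, 2, 8)) {
    sp <- chequerboard_spec(9.55, step, seed = 2)
    pos <- apparentmotion:::frame_positions(sp, 85, 1)
    n_events <- sum(diff(pos) != 0)
    expected <- floor(1 * 44.4 / step)
    expect_lte(abs(n_events - min(expected, 84)), 1)
  }
})

test_that("resolution and duration edge cases are caught", {
  sp <- chequerboard_spec(1, 0.02, seed = 1)
  expect_error(generate_stimulus(sp, geom, dx_deg = 0.3), "resolution")
  expect_error(generate_stimulus(sp, geom, dx_deg = 0.05), "resolution")
  sp2 <- chequerboard_spec(2, 50, duration_s = 1, seed = 1)
  expect_warning(generate_stimulus(sp2, geom), "duration")
  expect_error(spacetime_stimulus(matrix(-1, 2, 2), 0.1, 0.01), "negative")
  expect_error(spacetime_stimulus(matrix(NaN, 2, 2), 0.1, 0.01), "non-finite")
})

test_that("grating stimulus drifts at the requested frequencies", {
  g <- grating_stimulus(0.1, 5, extent_deg = 20, duration_s = 0.4)
  # one spatial period spans 10 deg = 200 samples
  expect_equal(g$luminance[1, 1], g$luminance[201, 1], tolerance = 1e-6)
  # one temporal period spans 200 ms
  expect_equal(g$luminance[1, 1], g$luminance[1, 201], tolerance = 1e-6)
})
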