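# Luminescence decay fitting, half-lives, detection window

test_that("the model evaluates a + b * 2^(c t)", {
  expect_equal(model_intensity(0, 3, 7, -0.1), 10)
  expect_equal(model_intensity(10000, 1000, 1000, -0.0001), 1500)
  expect_equal(model_intensity(c(0, 5, 50), 42, 0, -0.3), rep(42, 3))
})

test_that("noiseless generate-and-refit recovers the parameters", {
  params <- list(c(a = 1000, b = 1000, c = -0.0001),
                 c(a = 200, b = 5000, c = -0.00005),
                 c(a = 0, b = 800, c = -0.0004))
  for (p in params) {
    s <- generate_luminescence(p["a"], p["b"], p["c"], noise_sd = 0,
                               n_wells = 1)[[1]]
    f <- fit_decay(s, start = c(a = 1000, b = 1000, c = -0.0001))
    expect_true(f$converged)
    expect_lt(abs(f$a - p["a"]) / max(abs(p["a"]), 1), 1e-6)
    expect_lt(abs(f$b - p["b"]) / abs(p["b"]), 1e-6)
    expect_lt(abs(f$c - p["c"]) / abs(p["c"]), 1e-6)
  }
})

test_that("fits are equivariant to intensity rescaling", {
  s <- generate_luminescence(1200, 900, -0.00012, noise_sd = 5,
                             n_wells = 1, seed = 8)[[1]]
  f1 <- fit_decay(s)
  s10 <- luminescence_series(s$well_id, s$group, s$times, s$intensities * 10)
  f10 <- fit_decay(s10)
  expect_lt(abs(f10$a - 10 * f1$a) / abs(10 * f1$a), 1e-6)
  expect_lt(abs(f10$b - 10 * f1$b) / abs(10 * f1$b), 1e-6)
  expect_lt(abs(f10$c - f1$c) / abs(f1$c), 1e-6)
})

test_that("half-life is invariant to the time unit used in the fit", {
  s <- generate_luminescence(1000, 1000, -0.0001, noise_sd = 2,
                             n_wells = 1, seed = 3)[[1]]
  f_sec <- fit_decay(s)
  s_min <- luminescence_series(s$well_id, s$group, s$times / 60,
                               s$intensities)
  f_min <- fit_decay(s_min, start = c(a = 1000, b = 1000, c = -0.0001 * 60))
  expect_lt(abs(f_min$c - 60 * f_sec$c) / abs(60 * f_sec$c), 1e-6)
  expect_lt(abs(f_min$half_life * 60 - f_sec$half_life) / f_sec$half_life,
            1e-6)
})

test_that("degenerate series yield a flagged fit, not an error", {
  s <- luminescence_series("w1", "control", seq(0, 176 * 9, by = 176),
                           rep(500, 10))
  f <- fit_decay(s)
  expect_false(f$converged)
})

test_that("half_life converts the rate and flags non-decay", {
  expect_equal(half_life(nemaquant:::new_decay_fit(0, 1, -0.0001, 0, TRUE)),
               10000, ignore_attr = TRUE)
  expect_equal(half_life(nemaquant:::new_decay_fit(0, 1, -0.5, 0, TRUE)), 2,
               ignore_attr = TRUE)
  hl <- half_life(nemaquant:::new_decay_fit(0, 1, 0.001, 0, TRUE))
  expect_equal(as.numeric(hl), -1000)
  expect_true(attr(hl, "non_decaying"))
  hl0 <- half_life(nemaquant:::new_decay_fit(0, 1, 0, 0, TRUE))
  expect_true(is.na(hl0))
})

test_that("half-life comparison uses exact enumeration and reports exclusions", {
  mkfit <- function(c_val, conv = TRUE)
    nemaquant:::new_decay_fit(100, 100, c_val, 0, conv)
  tr_h <- c(3, 4, 5); ct_h <- c(1, 2)                  # hours
  tr <- lapply(-1 / (tr_h * 3600), mkfit)
  ct <- lapply(-1 / (ct_h * 3600), mkfit)
  cmp <- compare_half_lives(tr, ct)
  expect_equal(cmp$p_value, oracle_mw_exact(tr_h, ct_h), tolerance = 1e-12)

  identical_cmp <- suppressWarnings(
    compare_half_lives(lapply(c(-1e-4, -2e-4), mkfit),
                       lapply(c(-1e-4, -2e-4), mkfit)))
  expect_equal(identical_cmp$p_value, 1)

  expect_warning(
    cmp2 <- compare_half_lives(c(tr, list(mkfit(-1e-4, conv = FALSE),
                                          mkfit(2e-4))), ct),
    "excluded 2 treated")
  expect_equal(cmp2$n1, 3)
  expect_equal(cmp2$n_excluded_treated, 2)

  expect_error(compare_half_lives(list(mkfit(-1e-4)), ct), ">= 2 usable")
})

test_that("detection window separates contiguous and last significance", {
  grid_h <- 0.5  # short grid for speed
  treated <- generate_luminescence(1000, 4000, -0.0001, noise_sd = 30,
                                   duration_h = grid_h, n_wells = 6,
                                   group_label = "treated", seed = 5)
  control <- generate_luminescence(1000, 0, -0.0001, noise_sd = 30,
                                   duration_h = grid_h, n_wells = 6,
                                   group_label = "control", seed = 5,
                                   offset = 6)
  dw <- detection_window(treated, control)
  expect_gt(dw$conservative_end, 0)
  expect_lte(dw$conservative_end, dw$liberal_end)

  # a significant island after a gap pushes liberal_end past conservative_end
  times <- seq(0, 176 * 9, by = 176)
  hi <- function(at) vapply(seq_along(times), function(i)
    if (i %in% at) 2000 else 1000, numeric(1))
  mk <- function(id, group, at, jit)
    luminescence_series(id, group, times, hi(at) + jit)
  set.seed(77)
  tr <- lapply(1:4, function(i) mk(paste0("t", i), "treated", c(1, 2, 7, 8),
                                   rnorm(10, 0, 1)))
  ct <- lapply(1:4, function(i) mk(paste0("c", i), "control", integer(0),
                                   rnorm(10, 0, 1)))
  dw2 <- detection_window(tr, ct, alpha = 0.05)
  expect_equal(dw2$conservative_end, times[2])
  expect_equal(dw2$liberal_end, times[8])

  # conservative window grows with the treated amplitude
  ends <- vapply(c(1000, 4000, 16000), function(b) {
    trb <- generate_luminescence(1000, b, -0.0001, noise_sd = 30,
                                 duration_h = grid_h, n_wells = 6,
                                 group_label = "treated", seed = 5)
    detection_window(trb, control)$conservative_end
  }, numeric(1))
  expect_true(all(diff(ends) >= 0))

  bad <- generate_luminescence(duration_h = 0.25, n_wells = 6, seed = 1)
  expect_error(detection_window(treated, bad), "time grid")
})
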