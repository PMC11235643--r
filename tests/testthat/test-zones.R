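make_test <- function(power, lactate, hr = NULL) {
  hr <- hr %||% (60 + 0.4 * power)
  step_test(data.frame(power_w = power, lactate_mmol = lactate, hr_bpm = hr),
            vo2peak = 5, hr_at_50pct_vo2peak = 120,
            hr_at_100pct_vo2peak = 200)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("lactate curve fitting recovers its own model class and flags degeneracy", {
  p <- seq(150, 300, by = 25)
  beta <- c(2, -0.01, 4e-5, 1e-7)
  la <- beta[1] + beta[2] * p + beta[3] * p^2 + beta[4] * p^3
  cv <- fit_lactate_curve(make_test(p, la))
  expect_equal(cv$coefficients, beta, tolerance = 1e-6)
  # linear lactate: quadratic and cubic terms vanish
  cv2 <- fit_lactate_curve(make_test(p, 1 + 0.01 * p))
  expect_equal(cv2$coefficients[3] * mean(p)^2, 0, tolerance = 1e-8)
  expect_equal(cv2$coefficients[4] * mean(p)^3, 0, tolerance = 1e-8)
  # duplicate powers are a rank-deficient design
  dup <- make_test(c(150, 175, 200, 250, 300), rep(1, 5))
  dup$steps$power_w[2] <- 150
  expect_error(fit_lactate_curve(dup), "rank-deficient")
  # exponential-law test: fitted cubic is monotone over the tested range
  prof <- quiet_profile()
  cv3 <- fit_lactate_curve(generate_step_test(prof))
  grid <- seq(cv3$range[1], cv3$range[2], length.out = 500)
  expect_true(all(diff(cv3$predict(grid)) > 0))
})

test_that("LT1 matches a brute-force scan and is baseline-relative", {
  prof <- quiet_profile(lactate_b = 0.05, lactate_c = 0.015)
  tt <- generate_step_test(prof)
  cv <- fit_lactate_curve(tt)
  lt1 <- detect_lt1(tt, cv)
  expect_equal(lt1$power, oracle_lt1_scan(cv), tolerance = 0.1)
  expect_equal(lt1$lactate - lt1$baseline, 0.4, tolerance = 1e-6)
  # shifting all lactates up by 1 leaves LT1 power unchanged
  tt2 <- tt
  tt2$steps$lactate_mmol <- tt$steps$lactate_mmol + 1
  expect_equal(detect_lt1(tt2)$power, lt1$power, tolerance = 1e-6)
  # flat lactate never rises above baseline + 0.4
  flat <- make_test(seq(150, 300, 25), rep(1.2, 7))
  expect_error(detect_lt1(flat), "no LT1")
})

test_that("modified D-max equals the exhaustive-scan oracle and is translation invariant", {
  prof <- quiet_profile()
  tt <- generate_step_test(prof)
  cv <- fit_lactate_curve(tt)
  lt1 <- detect_lt1(tt, cv)
  lt2 <- detect_lt2_mod_dmax(tt, cv, lt1$power)
  expect_equal(lt2$power, oracle_lt2_scan(cv, lt1$power), tolerance = 1e-9)
  expect_gt(lt2$power, lt1$power)
  expect_gt(lt2$distance, 0)
  expect_false(lt2$boundary)
  # adding a constant to all lactates translates curve and chord together
  tt2 <- tt
  tt2$steps$lactate_mmol <- tt$steps$lactate_mmol + 2
  cv2 <- fit_lactate_curve(tt2)
  lt2b <- detect_lt2_mod_dmax(tt2, cv2, lt1$power)
  expect_equal(lt2b$power, lt2$power, tolerance = 0.11)
  expect_equal(lt2b$distance, lt2$distance, tolerance = 1e-6)
  # chord endpoints carry zero perpendicular distance, so a search interval
  # containing only endpoints flags a boundary solution
  expect_warning(detect_lt2_mod_dmax(tt, cv, cv$range[2] - 0.05), "boundary")
})

test_that("power-to-HR interpolation reproduces nodes, midpoints and the generating line", {
  p <- seq(150, 300, by = 25)
  tt <- make_test(p, 1 + 0.05 * exp(0.01 * p), hr = 60 + 0.4 * p)
  expect_equal(power_to_hr(tt, 200), 60 + 0.4 * 200)
  expect_equal(power_to_hr(tt, 187.5),
               mean(c(60 + 0.4 * 175, 60 + 0.4 * 200)))
  dense <- seq(150, 300, by = 0.5)
  expect_equal(power_to_hr(tt, dense), 60 + 0.4 * dense, tolerance = 1e-9)
  expect_error(power_to_hr(tt, 301), "refusing to extrapolate")
  expect_error(power_to_hr(tt, 100), "refusing to extrapolate")
})

test_that("zone construction gives the worked boundaries and enforces landmark order", {
  zm <- build_zone_model(lt1_hr = 150, lt2_hr = 180, hr50 = 120, hr100 = 200)
  expect_equal(zm$boundaries, c(120, 135, 150, 171, 183.6, 200))
  # contiguity is structural: shared bounds between neighbouring zones
  expect_true(all(diff(zm$boundaries) > 0))
  expect_error(build_zone_model(150, 197, 120, 200), "stay below")
  expect_error(build_zone_model(172, 180, 120, 200), "0.95|exceed")
  expect_error(build_zone_model(150, 140, 120, 200), "inconsistent")
})

test_that("thresholds respond monotonically to the lactate growth rate", {
  cs <- c(0.010, 0.013, 0.016, 0.019)
  pows <- t(vapply(cs, function(cc) {
    prof <- quiet_profile(lactate_c = cc)
    tt <- generate_step_test(prof)
    cv <- fit_lactate_curve(tt)
    lt1 <- detect_lt1(tt, cv)
    lt2 <- detect_lt2_mod_dmax(tt, cv, lt1$power)
    c(lt1$power, lt2$power)
  }, numeric(2)))
  expect_true(all(diff(pows[, 1]) < 0))
  expect_true(all(diff(pows[, 2]) < 0))
  expect_true(all(pows[, 1] < pows[, 2]))
})

test_that("full zone pipeline yields contiguous ordered zones anchored at the VO2peak landmarks", {
  for (sex in c("M", "F")) {
    tt <- generate_step_test(athlete_profile(sex = sex), seed = 3)
    zm <- zone_model_from_test(tt)
    b <- zm$boundaries
    expect_length(b, 6)
    expect_true(all(diff(b) > 0))
    expect_equal(b[1], tt$hr_at_50pct_vo2peak)
    expect_equal(b[6], tt$hr_at_100pct_vo2peak)
    thr <- attr(zm, "thresholds")
    expect_lt(thr$lt1$power, thr$lt2$power)
    expect_lt(thr$lt1$hr, thr$lt2$hr)
  }
  # power-scaled variant orders the same way
  cfg <- pipeline_config(lt2_scale_on = "power")
  zmp <- zone_model_from_test(generate_step_test(quiet_profile()), cfg)
  expect_true(all(diff(zmp$boundaries) > 0))
})
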