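test_that("band filters apply inclusive bounds", {
  expect_equal(filter_sr_band(c(10, 14, 20, 50, 51)),
               c(FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_true(all(filter_sr_band(runif(50, 14, 50))))
  expect_equal(filter_velocity_band(c(2.0, 2.1, 5.0, 7.0, 7.1)),
               c(FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_false(any(filter_velocity_band(rep(0.05, 10))))  # stationary boat
})

test_that("velocity smoothing is a trailing mean with an expanding head", {
  expect_equal(smooth_velocity(rep(3.3, 40)), rep(3.3, 40))
  v <- c(rep(0, 100), rep(1, 100))
  sm <- smooth_velocity(v)
  expect_lt(sm[114], 1)          # still inside the transition
  expect_equal(sm[115], 1)       # reaches 1 exactly 15 samples after the step
  expect_equal(sm, oracle_trailing_mean(v, 15))
  # smoothing a constant twice changes nothing
  expect_equal(smooth_velocity(smooth_velocity(rep(2, 30))), rep(2, 30))
  expect_error(smooth_velocity(1:5), "shorter than")
  expect_equal(smooth_velocity(c(1, 2, 3), allow_short = TRUE), c(1, 1.5, 2))
})

test_that("prognostic conversion is a linear percentage of world best", {
  tab <- tibble::tibble(boat_class = "1X", sex = "M", velocity_ms = 6.0)
  expect_equal(to_prognostic(4.8, "1X", "M", tab), 80)
  expect_equal(to_prognostic(6.0, "1X", "M", tab), 100)
  expect_equal(to_prognostic(2 * 1.7, "1X", "M", tab),
               2 * to_prognostic(1.7, "1X", "M", tab))
  expect_error(to_prognostic(4, "2X", "M", tab), "no world-best")
})

test_that("zone classification follows the upper-inclusive interval convention", {
  zm <- build_zone_model(150, 180, 120, 200)
  expect_equal(classify_zone(c(119, 120, 135, 140, 150, 171, 183.6, 200), zm),
               c("below", "T1", "T1", "T2", "T2", "T3", "T4", "T5"))
  expect_equal(classify_zone(205, zm), "T5")                      # clamp
  expect_equal(classify_zone(205, zm, above_t5 = "drop"), "above")
})

test_that("gradient filter requires both rapid-change conditions by default", {
  # constant stream: nothing removed
  expect_true(all(gradient_filter(0:59, rep(20, 60), rep(3, 60))))
  # stationary race start: SR 16 -> 32 and velocity 0 -> 4 over 5 s
  t <- 0:29
  sr <- c(rep(16, 10), seq(16, 32, length.out = 5), rep(32, 15))
  v <- c(rep(0.5, 10), seq(0.5, 4, length.out = 5), rep(4, 15))
  keep <- gradient_filter(t, sr, v)
  expect_equal(keep, oracle_gradient(t, sr, v))
  expect_false(all(keep[11:20]))  # transition points removed
  # a pure SR ramp with constant velocity survives AND semantics entirely
  ramp_sr <- seq(16, 40, length.out = 40)
  expect_true(all(gradient_filter(0:39, ramp_sr, rep(3, 40))))
  expect_false(all(gradient_filter(0:39, ramp_sr, rep(3, 40),
                                   pipeline_config(grad_connective = "or"))))
  # lookbacks resolve by timestamp: a gap disables the reference
  tg <- c(0:4, 10:14)
  expect_true(all(gradient_filter(tg, c(rep(16, 5), rep(40, 5)),
                                  c(rep(1, 5), rep(4, 5)))))
})

test_that("minimum-run filter removes short zone visits", {
  expect_false(any(min_run_filter(rep("T2", 14))))
  expect_true(all(min_run_filter(rep("T2", 15))))
  labs <- rep(c("T1", "T2", "T1"), c(20, 5, 20))
  expect_equal(min_run_filter(labs), rep(c(TRUE, FALSE, TRUE), c(20, 5, 20)))
  for (seed in 1:5) {
    set.seed(seed)
    labs <- sample(paste0("T", 1:3), 200, replace = TRUE, prob = c(.6, .3, .1))
    expect_equal(min_run_filter(labs), oracle_min_run(labs))
  }
})

test_that("a noiseless in-band in-zone session passes the cascade untouched", {
  prof <- quiet_profile()
  zm <- quiet_zone_model(prof)
  tpl <- flat_template(duration = 300, sr = 22, intensity = 0.4)
  b <- zm$boundaries
  s <- generate_session(prof, tpl, zm, hr0 = (b[2] + b[3]) / 2)
  cs <- clean_session(s, zm)
  ret <- attr(cs, "retention")
  expect_equal(ret$fraction, 1.0)
  expect_true(all(ret$stages == 0))
  expect_equal(nrow(cs), nrow(s))
})

test_that("cleaning removes generator artifacts: drills exactly, starts almost all", {
  prof <- quiet_profile()
  zm <- quiet_zone_model(prof)
  tpl <- standard_template("steady", duration_scale = 0.5, artifact_rate = 1.2)
  s <- generate_session(prof, tpl, zm, seed = 8)
  truth <- attr(s, "truth")
  # in a noiseless session the SR band removes only artifact seconds
  # (drills and the stationary hold of race starts), and every drill second
  band_removed <- !filter_sr_band(s$sr_spm)
  drill <- truth$artifact == "drill"
  expect_true(all(truth$artifact[band_removed] != "none"))
  expect_true(all(band_removed[drill]))
  cs <- clean_session(s, zm)
  removed <- setdiff(s$time_s, cs$time_s)
  art <- truth$time_s[truth$artifact != "none"]
  recall <- length(intersect(art, removed)) / length(art)
  precision <- length(intersect(art, removed)) / length(removed)
  expect_gt(recall, 0.8)
  expect_gt(precision, 0)
  expect_true(all(truth$time_s[drill] %in% removed))
})

test_that("cascade output satisfies its record-level invariants", {
  prof <- athlete_profile()
  zm <- zone_model_from_test(generate_step_test(prof, seed = 1))
  s <- generate_session(prof, standard_template("threshold",
                                                duration_scale = 0.4,
                                                artifact_rate = 0.8),
                        zm, seed = 3)
  cs <- clean_session(s, zm)
  # surviving records are a subset, in original order, never duplicated
  expect_true(all(cs$time_s %in% s$time_s))
  expect_false(any(duplicated(cs$time_s)))
  expect_true(all(diff(cs$time_s) > 0))
  expect_true(all(cs$sr_spm >= 14 & cs$sr_spm <= 50))
  expect_true(all(cs$velocity_smoothed >= 2.1 & cs$velocity_smoothed <= 7.0))
  expect_true(all(cs$zone %in% paste0("T", 1:5)))
  expect_true(all(cs$prognostic_velocity > 0))
  # retention accounting conserves counts exactly
  ret <- attr(cs, "retention")
  expect_identical(unname(sum(ret$stages)), ret$raw - ret$surviving)
})

test_that("filter order matters on artifact-laden sessions", {
  prof <- quiet_profile()
  zm <- quiet_zone_model(prof)
  s <- generate_session(prof, standard_template("race", duration_scale = 0.4,
                                                artifact_rate = 1.5),
                        zm, seed = 4)
  canonical <- attr(clean_session(s, zm), "retention")$fraction
  # alternative order: min-run before the gradient filter, composed by hand
  cfg <- pipeline_config()
  keep <- filter_sr_band(s$sr_spm, cfg$sr_band)
  d <- s[keep, ]
  vs <- smooth_velocity(d$velocity_ms, allow_short = TRUE)
  d <- d[filter_velocity_band(vs, cfg$vel_band), ]
  vs <- vs[filter_velocity_band(vs, cfg$vel_band)]
  z <- classify_zone(d$hr_bpm, zm)
  d <- d[z != "below", ]; vs <- vs[z != "below"]; z <- z[z != "below"]
  keep <- min_run_filter(z, cfg$min_run)
  d <- d[keep, ]; vs <- vs[keep]
  keep <- gradient_filter(d$time_s, d$sr_spm, vs, cfg)
  swapped <- sum(keep) / nrow(s)
  expect_false(isTRUE(all.equal(canonical, swapped)))
})

test_that("cleaning an entirely below-zone session warns and returns empty", {
  prof <- quiet_profile()
  zm <- quiet_zone_model(prof)
  s <- generate_session(prof, flat_template(duration = 200, sr = 20),
                        zm, hr0 = prof$hr_rest)
  # classify against a model sitting far above the session's heart rates
  high <- zone_model(c(190, 200, 210, 220, 230, 240))
  expect_warning(cs <- clean_session(s, high), "empty")
  expect_equal(nrow(cs), 0)
})
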