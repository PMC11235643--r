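make_clean_fixture <- function(seed = 1, athletes = 2, sessions = 2) {
  coh <- generate_cohort(athletes, sessions, seed = seed,
                         duration_scale = 0.25, artifact_rate = 0.3)
  clean_cohort(coh)
}

test_that("zone summary means match arithmetic and a group-by oracle", {
  d <- tibble::tibble(
    athlete_id = "A", session_id = "S1", date = as.Date("2023-09-01"),
    boat_class = "1X", time_s = 1:3, sr_spm = c(20, 20, 22),
    velocity_smoothed = 3.5, prognostic_velocity = 70,
    hr_bpm = 130, zone = "T1"
  )
  zs <- summarize_by_zone(d)
  expect_equal(nrow(zs), 1)
  expect_equal(zs$mean_sr, mean(c(20, 20, 22)))
  # group-by oracle on pooled cohort records
  cl <- make_clean_fixture()
  pooled <- bind_clean_streams(cl)
  zs <- summarize_by_zone(pooled)
  oracle <- aggregate(cbind(sr_spm, prognostic_velocity) ~
                        athlete_id + session_id + zone,
                      data = pooled, FUN = mean)
  merged <- merge(as.data.frame(zs), oracle,
                  by = c("athlete_id", "session_id", "zone"))
  expect_equal(nrow(merged), nrow(zs))
  expect_equal(merged$mean_sr, merged$sr_spm, tolerance = 1e-12)
  expect_equal(merged$mean_prog_vel, merged$prognostic_velocity,
               tolerance = 1e-12)
  # summarising sessions jointly equals summarising them separately
  single <- dplyr::bind_rows(lapply(cl, summarize_by_zone))
  expect_equal(nrow(single), nrow(zs))
})

test_that("overlap index behaves at its limits and is symmetric", {
  set.seed(42)
  x <- rnorm(1000)
  expect_gte(overlap_index(x, x), 0.99)
  far <- rnorm(1000, 500)
  expect_lt(overlap_index(x, far), 1e-6)
  y <- rnorm(1000, 1)
  expect_equal(overlap_index(x, y), overlap_index(y, x))
  eta <- overlap_index(x, y)
  expect_gte(eta, 0); expect_lte(eta, 1)
  expect_error(overlap_index(rep(1, 20), x), "degenerate")
  expect_error(overlap_index(x[1:5], y), "at least 10")
})

test_that("overlap matrix is symmetric with unit diagonal", {
  cl <- make_clean_fixture()
  m <- overlap_matrix(cl, "sr")
  expect_true(isSymmetric(m))
  present <- !is.na(diag(m))
  expect_true(all(diag(m)[present] == 1))
  off <- m[upper.tri(m)]
  expect_true(all(is.na(off) | (off >= 0 & off <= 1)))
})

test_that("mixed model recovers simulated zone means and athlete variance", {
  zs <- generate_zone_summary(8, 10, seed = 3)
  truth <- attr(zs, "truth")
  zc <- fit_zone_contrasts(zs, "mean_sr")
  expect_equal(nrow(zc$means), 5)
  expect_true(all(abs(zc$means$emmean - truth$zone_means_sr) <=
                    2 * zc$means$SE))
  expect_equal(nrow(zc$contrasts), 10)
  expect_true(all(zc$contrasts$p_adj >= zc$contrasts$p_raw - 1e-15))
  expect_equal(zc$ranef$athlete_sd, truth$athlete_sd_sr, tolerance = 0.6)
  # degenerate athlete variance is estimated near zero
  zs0 <- generate_zone_summary(8, 10, athlete_sd_sr = 0, seed = 4)
  zc0 <- fit_zone_contrasts(zs0, "mean_sr")
  expect_lt(zc0$ranef$athlete_sd, 0.3)
  # a single athlete falls back to fixed effects with a warning
  one <- zs[zs$athlete_id == "A01", ]
  expect_warning(zc1 <- fit_zone_contrasts(one, "mean_sr"), "single athlete")
  expect_true(is.na(zc1$ranef$athlete_sd))
})

test_that("stroke-rate bins follow the printed edges with nearest-spm rounding", {
  expect_equal(as.character(sr_bin_label(c(19, 21))), c("19-21", "19-21"))
  expect_equal(as.character(sr_bin_label(18.4)), "14-18")
  expect_equal(as.character(sr_bin_label(c(14, 50, 46))),
               c("14-18", "46-50", "46-50"))
  cl <- make_clean_fixture(seed = 6, athletes = 2, sessions = 3)
  pooled <- bind_clean_streams(cl)
  bins <- sr_bin_summary(pooled, "1X")
  if (nrow(bins)) {
    d <- pooled[pooled$boat_class == "1X", ]
    d$sr_bin <- sr_bin_label(d$sr_spm)
    oracle <- aggregate(sr_spm ~ athlete_id + session_id + sr_bin,
                        data = d[!is.na(d$sr_bin), ], FUN = mean)
    merged <- merge(as.data.frame(bins), oracle,
                    by = c("athlete_id", "session_id", "sr_bin"))
    expect_equal(nrow(merged), nrow(bins))
    expect_equal(merged$mean_sr, merged$sr_spm, tolerance = 1e-12)
  }
  expect_error(sr_bin_summary(pooled, "9X"), "unknown boat class")
})

test_that("correlation magnitudes follow the threshold table, boundaries upward", {
  x <- 1:10
  res <- correlate(x, 2 * x + 1)
  expect_equal(res$r, 1)
  expect_equal(res$magnitude, "perfect")
  expect_equal(correlation_magnitude(c(0.05, 0.1, 0.3, 0.5, 0.7, 0.9, 1)),
               c("trivial", "small", "moderate", "large", "very large",
                 "nearly perfect", "perfect"))
  expect_equal(correlation_magnitude(0.50), "large")
  expect_equal(correlation_magnitude(-0.62), "large")
  set.seed(1)
  a <- rnorm(50); b <- a + rnorm(50)
  expect_equal(correlate(a, b)$r, oracle_pearson(a, b), tolerance = 1e-12)
  expect_error(correlate(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(correlate(1:2, 2:3), "at least 3")
})

test_that("per-athlete correlations are computed within groups", {
  set.seed(2)
  g <- rep(c("A", "B"), each = 30)
  x <- rnorm(60)
  y <- ifelse(g == "A", x, -x) + rnorm(60, sd = 0.2)
  res <- correlate(x, y, by = g)
  expect_equal(nrow(res$per_group), 2)
  ra <- res$per_group$r[res$per_group$group == "A"]
  rb <- res$per_group$r[res$per_group$group == "B"]
  expect_gt(ra, 0.8); expect_lt(rb, -0.8)
})

test_that("progression requires temporal spread and responds to a trend", {
  coh <- generate_cohort(2, 6, seed = 12, duration_scale = 0.25,
                         artifact_rate = 0.2, trend_per_day = 0.002,
                         boat_class_freq = c("1X" = 1))
  cl <- clean_cohort(coh)
  res <- progression_at_sr20(cl)
  expect_s3_class(res, "correlation_result")
  expect_gt(res$r, 0)
  expect_true(!is.null(attr(res, "sessions")))
  # all sessions on one date: degenerate
  one <- attr(res, "sessions")[1, ]
  d <- bind_clean_streams(cl)
  d <- d[d$session_id == one$session_id, ]
  expect_error(progression_at_sr20(d), "single date")
})

test_that("retention report conserves counts across sessions", {
  cl <- make_clean_fixture(seed = 9)
  rep_ <- retention_report(cl)
  expect_equal(unname(sum(rep_$stages)), rep_$raw - rep_$surviving)
  expect_equal(rep_$overall_fraction, rep_$surviving / rep_$raw)
  expect_equal(nrow(rep_$per_session), length(cl))
  # artifact-free noiseless cohort retains everything
  prof <- quiet_profile()
  zm <- quiet_zone_model(prof)
  b <- zm$boundaries
  s <- generate_session(prof, flat_template(duration = 200, sr = 22,
                                            intensity = 0.4),
                        zm, hr0 = (b[2] + b[3]) / 2)
  expect_equal(retention_report(list(clean_session(s, zm)))$overall_fraction, 1)
})

test_that("figure builders return ggplot objects", {
  cl <- make_clean_fixture(seed = 10)
  expect_s3_class(plot_zone_distributions(cl, "sr"), "ggplot")
  bins <- sr_bin_summary(cl, "1X")
  if (nrow(bins)) expect_s3_class(plot_sr_velocity(bins), "ggplot")
})
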