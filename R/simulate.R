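#' Simulate an incremental ergometer step test
#'
#' Generates a graded 7 x 4 min style step test from an [athlete_profile()]:
#' per-step mean power, blood lactate drawn around the profile's exponential
#' curve `La(P) = a + b * exp(c * P)`, and heart rate drawn around the
#' profile's linear HR-power response (clipped at `hr_max`). The heart rates
#' at 50% and 100% VO2peak are derived from the profile's oxygen-uptake and
#' heart-rate lines and attached as landmarks.
#'
#' @param profile an [athlete_profile()].
#' @param n_steps number of steps (>= 5).
#' @param start_power power of the first step (W); default 150 (M) / 120 (F).
#' @param increment power increment per step (W, > 0); default 25 (M) / 20 (F).
#' @param seed optional integer seed; identical seeds give identical tests.
#'
#' @return A `step_test`: list with `steps` (tibble: `step`, `power_w`,
#'   `lactate_mmol`, `hr_bpm`), `vo2peak`, `hr_at_50pct_vo2peak`,
#'   `hr_at_100pct_vo2peak`, `athlete_id`.
#' @export
#' @examples
#' generate_step_test(athlete_profile(), seed = 1)
generate_step_test <- function(profile, n_steps = 7L,
                               start_power = NULL, increment = NULL,
                               seed = NULL) {
  stopifnot(inherits(profile, "athlete_profile"))
  if (n_steps < 5L) stop("n_steps must be >= 5", call. = FALSE)
  male <- profile$sex == "M"
  start_power <- start_power %||% if (male) 150 else 120
  increment <- increment %||% if (male) 25 else 20
  if (increment <= 0) stop("increment must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  power <- start_power + (seq_len(n_steps) - 1L) * increment
  lactate <- profile$lactate_a + profile$lactate_b * exp(profile$lactate_c * power) +
    rnorm(n_steps, 0, profile$noise_sd_lactate)
  hr <- pmin(profile$hr_intercept + profile$hr_slope * power +
               rnorm(n_steps, 0, profile$noise_sd_step_hr),
             profile$hr_max)

  p50 <- (0.5 * profile$vo2peak - profile$vo2_intercept) / profile$vo2_slope
  p100 <- (profile$vo2peak - profile$vo2_intercept) / profile$vo2_slope
  hr50 <- min(profile$hr_intercept + profile$hr_slope * p50, profile$hr_max)
  hr100 <- min(profile$hr_intercept + profile$hr_slope * p100, profile$hr_max)

  step_test(
    steps = tibble(step = seq_len(n_steps), power_w = power,
                   lactate_mmol = lactate, hr_bpm = hr),
    vo2peak = profile$vo2peak,
    hr_at_50pct_vo2peak = hr50,
    hr_at_100pct_vo2peak = hr100,
    athlete_id = profile$athlete_id
  )
}

#' Construct a step test
#'
#' Validates and packages an incremental-test table: at least five steps,
#' strictly increasing power, and an ordered pair of VO2peak heart-rate
#' landmarks.
#'
#' @param steps data frame with columns `step`, `power_w`, `lactate_mmol`,
#'   `hr_bpm`.
#' @param vo2peak peak oxygen uptake (L/min).
#' @param hr_at_50pct_vo2peak,hr_at_100pct_vo2peak heart rates (bpm) at 50%
#'   and 100% VO2peak; the former must be the smaller.
#' @param athlete_id identifier.
#' @return A list with class `step_test`.
#' @export
step_test <- function(steps, vo2peak, hr_at_50pct_vo2peak,
                      hr_at_100pct_vo2peak, athlete_id = "unknown") {
  steps <- as_tibble(steps)
  stopifnot(
    all(c("power_w", "lactate_mmol", "hr_bpm") %in% names(steps)),
    nrow(steps) >= 5L,
    all(diff(steps$power_w) > 0),
    all(is.finite(steps$lactate_mmol)),
    hr_at_50pct_vo2peak < hr_at_100pct_vo2peak
  )
  if (!"step" %in% names(steps)) steps$step <- seq_len(nrow(steps))
  structure(list(
    steps = steps, vo2peak = vo2peak,
    hr_at_50pct_vo2peak = hr_at_50pct_vo2peak,
    hr_at_100pct_vo2peak = hr_at_100pct_vo2peak,
    athlete_id = as.character(athlete_id)
  ), class = "step_test")
}

#' @export
print.step_test <- function(x, ...) {
  cat(sprintf("<step_test> %s: %d steps, %g-%g W; VO2peak %.2f L/min; HR@50%%/100%% = %.1f/%.1f bpm\n",
              x$athlete_id, nrow(x$steps), min(x$steps$power_w),
              max(x$steps$power_w), x$vo2peak,
              x$hr_at_50pct_vo2peak, x$hr_at_100pct_vo2peak))
  print(x$steps)
  invisible(x)
}

#' Simulate a 1 Hz on-water rowing session
#'
#' Produces a per-second stream of stroke rate, boat velocity and heart
#' rate for one session built from a [session_template()]. Within each
#' segment, stroke rate is the target plus Gaussian noise; velocity follows
#' the athlete's power law `v = k * SR^e` scaled by the boat-class speed
#' ratio, the environmental multiplier and multiplicative noise; heart rate
#' follows a first-order lag `dHR/dt = (HR_target - HR) / tau` towards a
#' target inside the segment's intended zone. Artifacts are inserted at the
#' template's per-minute rate: drill/turn blocks (stroke rate below 14 spm
#' and near-stationary velocity) and stationary race starts (step changes
#' of several spm per second and large velocity ramps). Ground truth
#' (segment id, artifact type, intended zone) is kept alongside the stream.
#'
#' @param profile an [athlete_profile()].
#' @param template a [session_template()].
#' @param zone_model a [zone_model()] for this athlete; must lie within the
#'   profile's resting-to-maximal heart-rate range.
#' @param seed optional integer seed.
#' @param date session date (`Date`).
#' @param hr_offset additive shift (bpm) applied to every segment heart-rate
#'   target before clamping into its zone (athlete-level random effect).
#' @param vel_scale extra multiplicative velocity scale (e.g. a fitness
#'   trend), applied on top of the template's `env_multiplier`.
#' @param hr0 initial heart rate (bpm); default `hr_rest + 30`.
#' @param world_best world-best velocity lookup (see
#'   [world_best_velocity()]); used for the boat-class speed ratio.
#'
#' @return A `session_stream`: tibble with columns `time_s`, `sr_spm`,
#'   `velocity_ms`, `hr_bpm` and attributes `athlete_id`, `date`,
#'   `boat_class`, and `truth` (tibble: `time_s`, `segment`, `artifact`,
#'   `intended_zone`).
#' @export
#' @examples
#' prof <- athlete_profile()
#' zm <- zone_model_from_test(generate_step_test(prof, seed = 1))
#' generate_session(prof, standard_template("steady", duration_scale = 0.2),
#'                  zm, seed = 2)
generate_session <- function(profile, template, zone_model, seed = NULL,
                             date = as.Date("2023-09-01"), hr_offset = 0,
                             vel_scale = 1, hr0 = NULL,
                             world_best = world_best_velocity()) {
  stopifnot(inherits(profile, "athlete_profile"),
            inherits(template, "session_template"),
            inherits(zone_model, "zone_model"))
  seg <- template$segments
  total <- sum(seg$duration_s)
  if (total < 120L) stop("template segments must total >= 120 s", call. = FALSE)
  b <- zone_model$boundaries
  if (b[1] < profile$hr_rest || b[6] > profile$hr_max) {
    stop("zone model does not fit inside the athlete's HR range", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  seg_of <- rep(seq_len(nrow(seg)), seg$duration_s)
  target_sr <- rep(seg$target_sr, seg$duration_s)
  zone_idx <- pmin(5L, pmax(1L, ceiling(5 * seg$intensity)))
  # HR target: zone midpoint + athlete offset, clamped 1 bpm inside the zone
  mid <- (b[zone_idx] + b[zone_idx + 1L]) / 2
  hr_target_seg <- pmin(pmax(mid + hr_offset, b[zone_idx] + 1), b[zone_idx + 1L] - 1)
  hr_target <- rep(hr_target_seg, seg$duration_s)
  intended <- rep(paste0("T", zone_idx), seg$duration_s)

  sr <- target_sr + rnorm(total, 0, profile$noise_sd_sr)
  sr <- pmax(sr, 1)
  class_mult <- boat_class_multiplier(template$boat_class, profile$sex, world_best)
  vel <- profile$vel_k * sr^profile$vel_e * template$env_multiplier *
    class_mult * vel_scale * (1 + rnorm(total, 0, profile$noise_sd_v))

  # artifacts overwrite stroke rate and velocity, and redirect the heart-rate
  # target: a drill/turn is near-rest work, a stationary start is maximal
  artifact <- rep("none", total)
  n_art <- if (template$artifact_rate > 0) rpois(1, template$artifact_rate * total / 60) else 0L
  if (n_art > 0) {
    starts <- sort(sample.int(total, n_art, replace = TRUE))
    kinds <- sample(c("start", "drill"), n_art, replace = TRUE,
                    prob = c(template$start_prob, 1 - template$start_prob))
    for (i in seq_len(n_art)) {
      if (kinds[i] == "drill") {
        dur <- sample(20:40, 1)
        idx <- starts[i]:min(total, starts[i] + dur - 1L)
        sr[idx] <- runif(length(idx), 6, 12)
        vel[idx] <- runif(length(idx), 0.3, 1.8)
        hr_target[idx] <- profile$hr_rest + 30
        artifact[idx] <- "drill"
      } else {
        # stationary race start: the crew sits at the line, then winds the
        # rate up from a standing boat at maximal effort
        hold <- sample(8:12, 1)
        ramp <- sample(10:15, 1)
        idx <- starts[i]:min(total, starts[i] + hold + ramp - 1L)
        m <- length(idx)
        mh <- min(hold, m)
        sr[idx[seq_len(mh)]] <- runif(mh, 0, 6)
        vel[idx[seq_len(mh)]] <- runif(mh, 0.05, 0.4)
        if (m > mh) {
          mr <- m - mh
          sr[idx[(mh + 1):m]] <- seq(16, 40, length.out = mr)
          vel[idx[(mh + 1):m]] <- seq(0.4, 4.5, length.out = mr)
          hr_target[idx[(mh + 1):m]] <- profile$hr_max - 5
        }
        artifact[idx] <- "start"
      }
    }
  }

  hr0 <- hr0 %||% (profile$hr_rest + 30)
  a1 <- 1 - 1 / profile$hr_lag_tau
  hr_state <- as.numeric(stats::filter(hr_target / profile$hr_lag_tau,
                                       a1, method = "recursive", init = hr0))
  hr <- hr_state + rnorm(total, 0, profile$noise_sd_hr)
  hr <- pmin(pmax(hr, profile$hr_rest - 10), profile$hr_max)

  records <- tibble(
    time_s = seq_len(total) - 1L,
    sr_spm = sr, velocity_ms = vel, hr_bpm = hr
  )
  truth <- tibble(
    time_s = records$time_s, segment = seg_of,
    artifact = artifact, intended_zone = intended
  )
  session_stream(records, athlete_id = profile$athlete_id, date = date,
                 boat_class = template$boat_class, sex = profile$sex,
                 truth = truth)
}

#' Construct a session stream
#'
#' A per-second record table with session metadata. Timestamps must be
#' strictly increasing; gaps (missing seconds) are permitted and flagged.
#'
#' @param records data frame with columns `time_s`, `sr_spm`,
#'   `velocity_ms`, `hr_bpm`.
#' @param athlete_id,date,boat_class session metadata.
#' @param sex athlete sex (`"M"`/`"F"`), used for the prognostic lookup.
#' @param truth optional ground-truth tibble (generator output).
#' @param session_id optional identifier; default `"<athlete>_<date>"`.
#' @return A tibble with class `session_stream` and metadata attributes.
#' @export
session_stream <- function(records, athlete_id, date, boat_class,
                           sex = "M", truth = NULL, session_id = NULL) {
  records <- as_tibble(records)
  stopifnot(
    all(c("time_s", "sr_spm", "velocity_ms", "hr_bpm") %in% names(records)),
    nrow(records) >= 1L, all(diff(records$time_s) > 0)
  )
  has_gaps <- nrow(records) > 1L && any(diff(records$time_s) != 1)
  structure(records,
            class = c("session_stream", class(records)),
            athlete_id = as.character(athlete_id),
            date = as.Date(date),
            boat_class = boat_class,
            sex = sex,
            truth = truth,
            has_gaps = has_gaps,
            session_id = session_id %||% paste0(athlete_id, "_", format(as.Date(date))))
}

#' @export
print.session_stream <- function(x, ...) {
  cat(sprintf("<session_stream> %s %s (%s): %d records (%d s)%s\n",
              attr(x, "athlete_id"), format(attr(x, "date")),
              attr(x, "boat_class"), nrow(x),
              x$time_s[nrow(x)] - x$time_s[1] + 1L,
              if (isTRUE(attr(x, "has_gaps"))) ", gaps present" else ""))
  NextMethod()
}

boat_class_multiplier <- function(boat_class, sex, world_best) {
  wb <- prognostic_lookup(world_best, boat_class, sex)
  wb1x <- prognostic_lookup(world_best, "1X", sex)
  wb / wb1x
}

#' Simulate a training cohort
#'
#' Builds `n_athletes` profiles (alternating male/female), one step test
#' and fitted zone model per athlete, and `sessions_per_athlete` sessions
#' per athlete spread over `span_days` days. Athlete heterogeneity enters
#' as a multiplicative log-normal random effect on the velocity coefficient
#' `k` and an additive Gaussian offset on segment heart-rate targets — the
#' minimal structure under which a random athlete intercept is meaningful
#' downstream. Session templates are drawn from [standard_template()] types
#' and boat classes from a configurable frequency table.
#'
#' @param n_athletes number of athletes (>= 1).
#' @param sessions_per_athlete sessions per athlete.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @param athlete_k_sd SD of the log-normal athlete effect on `vel_k`
#'   (0 = identical velocity laws).
#' @param athlete_hr_sd SD (bpm) of the athlete offset on heart-rate targets.
#' @param artifact_rate artifacts per minute passed to every template.
#' @param duration_scale scales session durations (1 = full-length sessions
#'   of roughly 40 min).
#' @param trend_per_day fractional velocity change per day (0 = no fitness
#'   trend; 0.001 = +0.1% per day).
#' @param boat_class_freq named numeric; sampling weights for boat classes.
#'   The default reflects a cohort rowing mostly small boats.
#' @param template_mix named numeric; sampling weights for the
#'   `"steady"`/`"threshold"`/`"race"` template types.
#' @param sr_by_zone target stroke rates for zones T1..T5 (spm).
#' @param sr_jitter per-segment half-width (spm) of the prescribed-rate
#'   variation between sessions (see [standard_template()]).
#' @param start_date first day of the observation period.
#' @param span_days length of the observation period (days).
#' @param world_best world-best velocity lookup table.
#'
#' @return A list with class `rowing_cohort`: `profiles`, `step_tests`,
#'   `zone_models` (named by athlete), `sessions` (list of
#'   `session_stream`), and `params`.
#' @export
#' @examples
#' coh <- generate_cohort(2, 2, seed = 1, duration_scale = 0.15)
#' length(coh$sessions)
generate_cohort <- function(n_athletes = 16L, sessions_per_athlete = 30L,
                            seed = 1L,
                            athlete_k_sd = 0.03, athlete_hr_sd = 3,
                            artifact_rate = 0.5, duration_scale = 1,
                            trend_per_day = 0,
                            boat_class_freq = c("1X" = 0.41, "2-" = 0.34,
                                                "2X" = 0.05, "4-" = 0.06,
                                                "4X" = 0.03, "8+" = 0.11),
                            template_mix = c(steady = 0.5, threshold = 0.3,
                                             race = 0.2),
                            sr_by_zone = c(20, 22, 25, 28, 31),
                            sr_jitter = 1.5,
                            start_date = as.Date("2023-09-01"),
                            span_days = 120L,
                            world_best = world_best_velocity()) {
  stopifnot(n_athletes >= 1L, sessions_per_athlete >= 1L,
            all(names(boat_class_freq) %in% boat_classes()))
  set.seed(seed)

  profiles <- lapply(seq_len(n_athletes), function(i) {
    athlete_profile(sprintf("A%02d", i), sex = if (i %% 2 == 1) "M" else "F")
  })
  names(profiles) <- vapply(profiles, `[[`, "", "athlete_id")
  k_mult <- exp(rnorm(n_athletes, 0, athlete_k_sd))
  hr_off <- rnorm(n_athletes, 0, athlete_hr_sd)
  for (i in seq_len(n_athletes)) profiles[[i]]$vel_k <- profiles[[i]]$vel_k * k_mult[i]

  # every cohort athlete must own a consistent zone model, as a completed
  # threshold-test protocol guarantees in practice; measurement noise can
  # occasionally push the detected landmarks out of order, in which case the
  # test is redrawn (a re-test)
  step_tests <- vector("list", n_athletes)
  zone_models <- vector("list", n_athletes)
  for (i in seq_len(n_athletes)) {
    for (attempt in 1:25) {
      tt <- generate_step_test(profiles[[i]])
      zm <- try(suppressWarnings(zone_model_from_test(tt)), silent = TRUE)
      if (!inherits(zm, "try-error")) break
    }
    if (inherits(zm, "try-error")) {
      stop("could not obtain a consistent zone model for athlete ",
           profiles[[i]]$athlete_id, call. = FALSE)
    }
    step_tests[[i]] <- tt
    zone_models[[i]] <- zm
  }
  names(step_tests) <- names(profiles)
  names(zone_models) <- names(profiles)

  sessions <- list()
  for (i in seq_len(n_athletes)) {
    days <- sort(sample.int(span_days, sessions_per_athlete, replace = TRUE)) - 1L
    types <- sample(names(template_mix), sessions_per_athlete,
                    replace = TRUE, prob = template_mix)
    classes <- sample(names(boat_class_freq), sessions_per_athlete,
                      replace = TRUE, prob = boat_class_freq)
    for (j in seq_len(sessions_per_athlete)) {
      tpl <- standard_template(types[j], sr_by_zone = sr_by_zone,
                               sr_jitter = sr_jitter,
                               duration_scale = duration_scale,
                               artifact_rate = artifact_rate,
                               env_multiplier = runif(1, 0.94, 1.06),
                               boat_class = classes[j])
      s <- generate_session(profiles[[i]], tpl, zone_models[[i]],
                            date = start_date + days[j],
                            hr_offset = hr_off[i],
                            vel_scale = 1 + trend_per_day * days[j],
                            world_best = world_best)
      attr(s, "session_id") <- sprintf("%s_S%03d", profiles[[i]]$athlete_id, j)
      sessions[[length(sessions) + 1L]] <- s
    }
  }

  structure(list(
    profiles = profiles, step_tests = step_tests, zone_models = zone_models,
    sessions = sessions,
    params = list(seed = seed, n_athletes = n_athletes,
                  sessions_per_athlete = sessions_per_athlete,
                  athlete_k_sd = athlete_k_sd, athlete_hr_sd = athlete_hr_sd,
                  artifact_rate = artifact_rate, trend_per_day = trend_per_day,
                  sr_by_zone = sr_by_zone, start_date = start_date,
                  span_days = span_days)
  ), class = "rowing_cohort")
}

#' @export
print.rowing_cohort <- function(x, ...) {
  cat(sprintf("<rowing_cohort> %d athletes, %d sessions (seed %s)\n",
              length(x$profiles), length(x$sessions),
              format(x$params$seed)))
  invisible(x)
}

#' Simulate session-by-zone summary rows directly
#'
#' Draws per-(athlete, session, zone) mean stroke rate and mean prognostic
#' velocity from the linear model `mean = zone_mean + athlete_intercept +
#' residual`, the exact data-generating process assumed by
#' [fit_zone_contrasts()]. Useful for parameter-recovery checks of the
#' mixed model without simulating raw streams.
#'
#' @param n_athletes,sessions_per_athlete cohort dimensions.
#' @param zone_means_sr,zone_means_vel true zone means for T1..T5
#'   (spm, % of world best).
#' @param athlete_sd_sr,resid_sd_sr,athlete_sd_vel,resid_sd_vel SDs of the
#'   athlete intercepts and residuals for the two responses.
#' @param seed integer seed.
#' @return A `zone_summary` tibble (`athlete_id`, `session_id`, `zone`,
#'   `mean_sr`, `mean_prog_vel`) with the true parameters in attribute
#'   `truth`.
#' @export
#' @examples
#' generate_zone_summary(4, 5, seed = 1)
generate_zone_summary <- function(n_athletes = 16L, sessions_per_athlete = 30L,
                                  zone_means_sr = c(20, 22, 25, 28, 31),
                                  zone_means_vel = c(66, 73, 79, 84, 86),
                                  athlete_sd_sr = 1.5, resid_sd_sr = 2,
                                  athlete_sd_vel = 3, resid_sd_vel = 5,
                                  seed = 1L) {
  stopifnot(length(zone_means_sr) == 5L, length(zone_means_vel) == 5L)
  set.seed(seed)
  zones <- paste0("T", 1:5)
  a_sr <- rnorm(n_athletes, 0, athlete_sd_sr)
  a_vel <- rnorm(n_athletes, 0, athlete_sd_vel)
  out <- tidyr::expand_grid(
    athlete = seq_len(n_athletes),
    session = seq_len(sessions_per_athlete),
    zone_i = 1:5
  )
  n <- nrow(out)
  res <- tibble(
    athlete_id = sprintf("A%02d", out$athlete),
    session_id = sprintf("A%02d_S%03d", out$athlete, out$session),
    zone = factor(zones[out$zone_i], levels = zones),
    mean_sr = zone_means_sr[out$zone_i] + a_sr[out$athlete] +
      rnorm(n, 0, resid_sd_sr),
    mean_prog_vel = zone_means_vel[out$zone_i] + a_vel[out$athlete] +
      rnorm(n, 0, resid_sd_vel)
  )
  structure(res,
            class = c("zone_summary", class(res)),
            truth = list(zone_means_sr = zone_means_sr,
                         zone_means_vel = zone_means_vel,
                         athlete_sd_sr = athlete_sd_sr,
                         athlete_sd_vel = athlete_sd_vel,
                         resid_sd_sr = resid_sd_sr,
                         resid_sd_vel = resid_sd_vel))
}
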