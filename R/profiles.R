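#' Athlete profile for the synthetic-data generator
#'
#' Describes one simulated rower: a heart-rate response line (HR linear in
#' ergometer power, clipped at `hr_max`), an oxygen-uptake line used to
#' locate 50% and 100% VO2peak, an exponential blood-lactate curve
#' `La(P) = a + b * exp(c * P)`, and an on-water stroke-rate to velocity
#' power law `v = k * SR^e` (single scull, neutral conditions). Defaults by
#' sex give landmark orderings typical of highly trained under-23 rowers:
#' LT1 near 160 bpm, LT2 near 180 bpm, 50% VO2peak in the high 120s.
#'
#' @param athlete_id identifier (character).
#' @param sex `"M"` or `"F"`; sets every default not supplied explicitly.
#' @param hr_max,hr_rest maximal and resting heart rate (bpm).
#' @param hr_intercept,hr_slope heart-rate response line: HR(P) =
#'   `hr_intercept + hr_slope * P`, clipped at `hr_max` (bpm, bpm/W).
#' @param vo2peak peak oxygen uptake (L/min).
#' @param vo2_intercept,vo2_slope oxygen-uptake line VO2(P) =
#'   `vo2_intercept + vo2_slope * P` (L/min, L/min/W), used to find the
#'   powers at 50% and 100% VO2peak.
#' @param lactate_a,lactate_b,lactate_c exponential lactate-curve
#'   parameters (mmol/L, mmol/L, 1/W); `b > 0`, `c > 0`.
#' @param vel_k,vel_e stroke-rate to velocity law `v = k * SR^e`
#'   (m/s per spm^e, dimensionless); `k > 0`, `0 < e < 1.5`.
#' @param hr_lag_tau first-order heart-rate lag time constant (s).
#' @param noise_sd_sr,noise_sd_hr per-second additive noise SD on stroke
#'   rate (spm) and observed heart rate (bpm).
#' @param noise_sd_v relative SD of the multiplicative velocity noise
#'   (dimensionless; velocity is scaled by `1 + N(0, noise_sd_v)`).
#' @param noise_sd_lactate,noise_sd_step_hr step-test noise SDs for lactate
#'   (mmol/L) and step heart rate (bpm).
#'
#' @return A list with class `athlete_profile`.
#' @export
#' @examples
#' athlete_profile("A01", sex = "F")
athlete_profile <- function(athlete_id = "A01",
                            sex = c("M", "F"),
                            hr_max = NULL, hr_rest = NULL,
                            hr_intercept = NULL, hr_slope = NULL,
                            vo2peak = NULL, vo2_intercept = NULL,
                            vo2_slope = 0.010,
                            lactate_a = 1.0, lactate_b = NULL,
                            lactate_c = NULL,
                            vel_k = NULL, vel_e = 0.55,
                            hr_lag_tau = 30,
                            noise_sd_sr = 0.8, noise_sd_hr = 2,
                            noise_sd_v = 0.02,
                            noise_sd_lactate = 0.15,
                            noise_sd_step_hr = 2) {
  sex <- match.arg(sex)
  male <- sex == "M"
  hr_max <- hr_max %||% if (male) 195 else 198
  hr_rest <- hr_rest %||% 50
  hr_intercept <- hr_intercept %||% if (male) 38 else 63
  hr_slope <- hr_slope %||% if (male) 0.53 else 0.56
  vo2peak <- vo2peak %||% if (male) 5.42 else 3.64
  vo2_intercept <- vo2_intercept %||% if (male) 1.0 else 0.8
  lactate_b <- lactate_b %||% 0.04
  lactate_c <- lactate_c %||% if (male) 0.012 else 0.016
  vel_k <- vel_k %||% if (male) 0.675 else 0.595

  stopifnot(
    hr_rest < hr_max, lactate_b > 0, lactate_c > 0,
    vel_k > 0, vel_e > 0, vel_e < 1.5, hr_lag_tau > 0,
    hr_slope > 0, vo2_slope > 0, vo2peak > vo2_intercept
  )
  structure(list(
    athlete_id = as.character(athlete_id), sex = sex,
    hr_max = hr_max, hr_rest = hr_rest,
    hr_intercept = hr_intercept, hr_slope = hr_slope,
    vo2peak = vo2peak, vo2_intercept = vo2_intercept, vo2_slope = vo2_slope,
    lactate_a = lactate_a, lactate_b = lactate_b, lactate_c = lactate_c,
    vel_k = vel_k, vel_e = vel_e, hr_lag_tau = hr_lag_tau,
    noise_sd_sr = noise_sd_sr, noise_sd_hr = noise_sd_hr,
    noise_sd_v = noise_sd_v, noise_sd_lactate = noise_sd_lactate,
    noise_sd_step_hr = noise_sd_step_hr
  ), class = "athlete_profile")
}

#' @export
print.athlete_profile <- function(x, ...) {
  cat(sprintf("<athlete_profile> %s (%s)\n", x$athlete_id, x$sex))
  cat(sprintf("  HR %d-%d bpm (HR = %.1f + %.3f P); VO2peak %.2f L/min\n",
              round(x$hr_rest), round(x$hr_max), x$hr_intercept, x$hr_slope,
              x$vo2peak))
  cat(sprintf("  La(P) = %.2f + %.3f exp(%.4f P); v = %.3f SR^%.2f; tau = %g s\n",
              x$lactate_a, x$lactate_b, x$lactate_c, x$vel_k, x$vel_e,
              x$hr_lag_tau))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Session template for the synthetic-data generator
#'
#' An ordered list of workout segments, each with a duration, a target
#' stroke rate and an intensity scalar in (0, 1] that selects the intended
#' heart-rate zone (`ceiling(5 * intensity)`, i.e. 0.2 -> T1 ... 1.0 -> T5).
#' Boat-class and environmental effects scale velocity multiplicatively.
#'
#' @param segments data frame with columns `duration_s`, `target_sr`
#'   (spm, within \[10, 55\]) and `intensity` (in (0, 1\]).
#' @param artifact_rate expected number of inserted artifacts (drill/turn
#'   blocks and stationary race starts) per minute of session.
#' @param start_prob probability that an inserted artifact is a stationary
#'   race start rather than a drill/turn block; race starts belong almost
#'   exclusively to race-practice sessions.
#' @param env_multiplier dimensionless velocity scale in \[0.8, 1.2\]
#'   (headwind < 1, tailwind > 1).
#' @param boat_class one of `"1X"`, `"2-"`, `"2X"`, `"4-"`, `"4X"`, `"8+"`.
#'
#' @return A list with class `session_template`.
#' @export
#' @examples
#' session_template(data.frame(
#'   duration_s = c(300, 900), target_sr = c(18, 22), intensity = c(0.2, 0.4)
#' ))
session_template <- function(segments,
                             artifact_rate = 0.5,
                             start_prob = 0.1,
                             env_multiplier = 1,
                             boat_class = "1X") {
  segments <- as.data.frame(segments)
  stopifnot(
    all(c("duration_s", "target_sr", "intensity") %in% names(segments)),
    nrow(segments) >= 1L,
    all(segments$duration_s > 0),
    all(segments$target_sr >= 10 & segments$target_sr <= 55),
    all(segments$intensity > 0 & segments$intensity <= 1),
    artifact_rate >= 0,
    start_prob >= 0, start_prob <= 1,
    env_multiplier >= 0.8, env_multiplier <= 1.2,
    boat_class %in% boat_classes()
  )
  segments$duration_s <- as.integer(round(segments$duration_s))
  structure(list(
    segments = segments,
    artifact_rate = artifact_rate,
    start_prob = start_prob,
    env_multiplier = env_multiplier,
    boat_class = boat_class
  ), class = "session_template")
}

#' The six Olympic-class boat codes
#'
#' Single scull (1X), coxless pair (2-), double scull (2X), coxless four
#' (4-), quadruple scull (4X), coxed eight (8+).
#'
#' @return Character vector of the six boat-class codes.
#' @export
boat_classes <- function() c("1X", "2-", "2X", "4-", "4X", "8+")

#' Built-in session templates
#'
#' Three canonical on-water session shapes used by [generate_cohort()]:
#' `"steady"` (low stroke-rate aerobic work in T1/T2), `"threshold"`
#' (T3/T4 intervals off a T1 base) and `"race"` (T5 bursts with T2
#' recoveries). Target stroke rates per zone default to 20/22/25/28/31 spm
#' for T1..T5.
#'
#' @param type one of `"steady"`, `"threshold"`, `"race"`.
#' @param sr_by_zone numeric length 5; target stroke rate for segments
#'   aimed at zones T1..T5.
#' @param sr_jitter half-width (spm) of a uniform per-segment perturbation
#'   of the target stroke rate, emulating session-to-session variation in
#'   the prescribed rate band (coaches prescribe ranges such as 18--20 spm
#'   that differ between days); 0 = exact zone targets.
#' @param duration_scale multiplies every segment duration (use < 1 for
#'   short test sessions).
#' @param ... passed to [session_template()] (`artifact_rate`,
#'   `env_multiplier`, `boat_class`). Unless overridden, `start_prob` is
#'   0.4 for race-practice sessions and 0.02 otherwise: stationary race
#'   starts are rehearsed in race sessions and rare elsewhere, while
#'   drill/turn blocks occur in every session type.
#'
#' @return A `session_template`.
#' @export
#' @examples
#' standard_template("threshold", duration_scale = 0.25)
standard_template <- function(type = c("steady", "threshold", "race"),
                              sr_by_zone = c(20, 22, 25, 28, 31),
                              sr_jitter = 0, duration_scale = 1, ...) {
  type <- match.arg(type)
  stopifnot(length(sr_by_zone) == 5L, sr_jitter >= 0, duration_scale > 0)
  zone_int <- c(0.2, 0.4, 0.6, 0.8, 1.0)
  seg <- function(dur, zone) {
    data.frame(duration_s = dur, target_sr = sr_by_zone[zone],
               intensity = zone_int[zone])
  }
  segments <- switch(type,
    steady = rbind(seg(300, 1), seg(900, 2), seg(300, 1), seg(900, 2)),
    threshold = rbind(
      seg(420, 1),
      seg(360, 3), seg(120, 1), seg(360, 3), seg(120, 1),
      seg(360, 4), seg(120, 1), seg(360, 4),
      seg(300, 1)
    ),
    race = {
      # alternating race-pace and sprint-rate pieces: under-23 race work sits
      # at and above the top zone-target rate
      sprint <- data.frame(duration_s = 120,
                           target_sr = min(sr_by_zone[5] + 5, 42),
                           intensity = zone_int[5])
      rbind(
        seg(600, 1),
        seg(180, 5), seg(180, 2),
        sprint, seg(180, 2),
        seg(180, 5), seg(180, 2),
        sprint, seg(180, 2),
        seg(300, 1)
      )
    }
  )
  segments$duration_s <- pmax(30L, as.integer(round(segments$duration_s * duration_scale)))
  if (sr_jitter > 0) {
    segments$target_sr <- pmin(pmax(
      segments$target_sr + runif(nrow(segments), -sr_jitter, sr_jitter),
      14.5), 49.5)
  }
  args <- list(...)
  if (is.null(args$start_prob)) {
    args$start_prob <- if (type == "race") 0.4 else 0.02
  }
  do.call(session_template, c(list(segments), args))
}
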