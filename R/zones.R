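#' Fit the blood lactate versus power curve
#'
#' Least-squares cubic polynomial of lactate concentration on step power,
#' the conventional smooth curve underlying D-max style threshold
#' detection on a 7-step incremental test.
#'
#' @param test a [step_test()].
#' @return A list with class `lactate_curve`: `coefficients` (intercept,
#'   linear, quadratic, cubic), `fitted` values at the step powers,
#'   `predict(power)` closure, and the fitted power `range`.
#' @export
#' @examples
#' fit_lactate_curve(generate_step_test(athlete_profile(), seed = 1))
fit_lactate_curve <- function(test) {
  stopifnot(inherits(test, "step_test"))
  p <- test$steps$power_w
  la <- test$steps$lactate_mmol
  if (anyDuplicated(p)) {
    stop("duplicate step powers: design is rank-deficient", call. = FALSE)
  }
  fit <- lm(la ~ poly(p, 3, raw = TRUE))
  beta <- unname(coef(fit))
  if (anyNA(beta)) stop("lactate curve fit is rank-deficient", call. = FALSE)
  structure(list(
    coefficients = beta,
    fitted = unname(predict(fit)),
    predict = function(power) {
      beta[1] + beta[2] * power + beta[3] * power^2 + beta[4] * power^3
    },
    range = range(p)
  ), class = "lactate_curve")
}

#' @export
print.lactate_curve <- function(x, ...) {
  cat(sprintf("<lactate_curve> La(P) = %.4g + %.4g P + %.4g P^2 + %.4g P^3 on [%g, %g] W\n",
              x$coefficients[1], x$coefficients[2], x$coefficients[3],
              x$coefficients[4], x$range[1], x$range[2]))
  invisible(x)
}

#' Detect the first lactate threshold (LT1)
#'
#' LT1 is the lowest power at which the fitted lactate curve exceeds the
#' baseline lactate by a fixed rise (default 0.4 mmol/L). The search scans
#' a dense power grid for the first crossing and refines it by bisection;
#' ties (grid resolution) resolve towards the lower power. The baseline is
#' the fitted curve value at the first step power by default (or the
#' observed first-step lactate, see [pipeline_config()]).
#'
#' @param test a [step_test()].
#' @param curve a [fit_lactate_curve()] result; fitted if missing.
#' @param config a [pipeline_config()] (`lt1_rise`, `lt1_baseline`,
#'   `dmax_grid`).
#' @return List: `power` (W), `hr` (bpm via [power_to_hr()]), `baseline`,
#'   `lactate` at threshold.
#' @export
#' @examples
#' tt <- generate_step_test(athlete_profile(noise_sd_lactate = 0,
#'                                          noise_sd_step_hr = 0))
#' detect_lt1(tt)
detect_lt1 <- function(test, curve = fit_lactate_curve(test),
                       config = pipeline_config()) {
  stopifnot(inherits(test, "step_test"), inherits(curve, "lactate_curve"))
  p1 <- curve$range[1]
  pn <- curve$range[2]
  baseline <- switch(config$lt1_baseline,
    fitted = curve$predict(p1),
    observed = test$steps$lactate_mmol[1]
  )
  thr <- baseline + config$lt1_rise
  grid <- seq(p1, pn, by = config$dmax_grid)
  above <- curve$predict(grid) >= thr
  if (!any(above)) {
    stop("no LT1: fitted curve never rises ", config$lt1_rise,
         " mmol/L above baseline within the tested range", call. = FALSE)
  }
  i <- which(above)[1]
  power <- if (i == 1L) grid[1] else {
    # bisection inside the bracketing grid cell
    lo <- grid[i - 1L]; hi <- grid[i]
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (curve$predict(mid) >= thr) hi <- mid else lo <- mid
      if (hi - lo < 1e-9) break
    }
    hi
  }
  list(power = power, hr = power_to_hr(test, power),
       baseline = baseline, lactate = curve$predict(power))
}

#' Detect the second lactate threshold (modified D-max)
#'
#' LT2 is the power maximising the perpendicular distance between the
#' fitted lactate curve and the chord joining the LT1 point to the final
#' step point — the modified D-max construction, which anchors the chord at
#' the first-rise point rather than at the first data point. The argmax is
#' searched on a dense power grid (spacing `config$dmax_grid`, default
#' 0.1 W) with ties broken towards the lower power. Distances are computed
#' in raw axis units (W, mmol/L).
#'
#' @param test a [step_test()].
#' @param curve a [fit_lactate_curve()] result; fitted if missing.
#' @param lt1_power chord anchor power (W); detected if missing.
#' @param config a [pipeline_config()].
#' @return List: `power` (W), `hr` (bpm), `distance` (the maximal
#'   perpendicular distance), `boundary` (TRUE with a warning when the
#'   argmax sits at an endpoint, i.e. the curve bends the wrong way).
#' @export
#' @examples
#' tt <- generate_step_test(athlete_profile(noise_sd_lactate = 0,
#'                                          noise_sd_step_hr = 0))
#' detect_lt2_mod_dmax(tt)
detect_lt2_mod_dmax <- function(test, curve = fit_lactate_curve(test),
                                lt1_power = NULL,
                                config = pipeline_config()) {
  stopifnot(inherits(test, "step_test"), inherits(curve, "lactate_curve"))
  if (is.null(lt1_power)) lt1_power <- detect_lt1(test, curve, config)$power
  pn <- curve$range[2]
  if (lt1_power < curve$range[1] || lt1_power >= pn) {
    stop("lt1_power must lie within the tested power range", call. = FALSE)
  }
  grid <- seq(lt1_power, pn, by = config$dmax_grid)
  if (grid[length(grid)] < pn) grid <- c(grid, pn)
  la <- curve$predict(grid)
  # perpendicular distance from (P, La(P)) to the chord LT1 -> final point
  x1 <- lt1_power; y1 <- curve$predict(lt1_power)
  x2 <- pn; y2 <- curve$predict(pn)
  d <- abs((y2 - y1) * grid - (x2 - x1) * la + x2 * y1 - y2 * x1) /
    sqrt((y2 - y1)^2 + (x2 - x1)^2)
  i <- which.max(d)  # which.max takes the first maximum: lower-power tie-break
  boundary <- i == 1L || i == length(grid)
  if (boundary) {
    warning("modified D-max maximum lies at the search boundary; ",
            "lactate curve may bend the wrong way", call. = FALSE)
  }
  list(power = grid[i], hr = power_to_hr(test, grid[i]),
       distance = d[i], boundary = boundary)
}

#' Map power to heart rate along the step-test response
#'
#' Piecewise-linear interpolation of step mean heart rate against step
#' power. Extrapolation outside the tested power range is refused.
#'
#' @param test a [step_test()].
#' @param power power (W), scalar or vector, within the tested range.
#' @return Heart rate(s) in bpm.
#' @export
power_to_hr <- function(test, power) {
  stopifnot(inherits(test, "step_test"))
  p <- test$steps$power_w
  if (any(power < p[1] - 1e-9) || any(power > p[length(p)] + 1e-9)) {
    stop("power outside the tested range [", p[1], ", ", p[length(p)],
         "] W: refusing to extrapolate", call. = FALSE)
  }
  approx(p, test$steps$hr_bpm, xout = power, rule = 1)$y
}

#' Build a five-zone heart-rate training model
#'
#' Constructs the contiguous zones T1..T5 from four landmarks: the heart
#' rates at 50% and 100% VO2peak and at the two lactate thresholds. T1
#' spans 50% VO2peak to the midpoint between 50% VO2peak and LT1; T2 ends
#' at LT1; T3 ends at 95% of LT2; T4 ends at 102% of LT2; T5 ends at 100%
#' VO2peak. By default the 95%/102% fractions apply to the heart rate at
#' LT2.
#'
#' @param lt1_hr,lt2_hr heart rates (bpm) at LT1 and LT2.
#' @param hr50,hr100 heart rates (bpm) at 50% and 100% VO2peak.
#' @param athlete_id identifier stored with the model.
#' @param config a [pipeline_config()] (`t4_lower_frac`, `t4_upper_frac`).
#' @return A [zone_model()].
#' @export
#' @examples
#' build_zone_model(150, 180, 120, 200)  # boundaries 120/135/150/171/183.6/200
build_zone_model <- function(lt1_hr, lt2_hr, hr50, hr100,
                             athlete_id = "unknown",
                             config = pipeline_config()) {
  if (!(hr50 < lt1_hr && lt1_hr < lt2_hr && lt2_hr < hr100)) {
    stop("inconsistent landmarks: need hr50 < lt1_hr < lt2_hr < hr100",
         call. = FALSE)
  }
  t3_top <- config$t4_lower_frac * lt2_hr
  t4_top <- config$t4_upper_frac * lt2_hr
  if (t3_top <= lt1_hr) {
    stop("inconsistent landmarks: ", config$t4_lower_frac,
         " * lt2_hr must exceed lt1_hr", call. = FALSE)
  }
  if (t4_top >= hr100) {
    stop("inconsistent landmarks: ", config$t4_upper_frac,
         " * lt2_hr must stay below hr100", call. = FALSE)
  }
  zone_model(
    boundaries = c(hr50, (hr50 + lt1_hr) / 2, lt1_hr, t3_top, t4_top, hr100),
    athlete_id = athlete_id,
    landmarks = list(hr50 = hr50, lt1_hr = lt1_hr, lt2_hr = lt2_hr,
                     hr100 = hr100)
  )
}

#' Construct a zone model
#'
#' Six strictly increasing heart-rate boundaries defining five contiguous
#' zones T1..T5. Intervals are upper-inclusive (zone Ti is
#' `(b[i], b[i+1]]`) except that T1 also includes its lower bound.
#'
#' @param boundaries numeric length 6, strictly increasing (bpm).
#' @param athlete_id identifier.
#' @param landmarks optional named list of the source landmarks.
#' @return A list with class `zone_model`.
#' @export
zone_model <- function(boundaries, athlete_id = "unknown", landmarks = NULL) {
  boundaries <- as.numeric(boundaries)
  stopifnot(length(boundaries) == 6L, all(diff(boundaries) > 0))
  structure(list(boundaries = boundaries,
                 athlete_id = as.character(athlete_id),
                 landmarks = landmarks),
            class = "zone_model")
}

#' @export
print.zone_model <- function(x, ...) {
  b <- x$boundaries
  cat(sprintf("<zone_model> %s\n", x$athlete_id))
  lab <- c(sprintf("  T1 [%g, %g]", b[1], b[2]),
           sprintf("  T%d (%g, %g]", 2:5, b[2:5], b[3:6]))
  cat(paste(lab, collapse = "\n"), "\n")
  invisible(x)
}

#' Derive a zone model from a step test
#'
#' Runs the full landmark pipeline: cubic lactate-curve fit, LT1 first-rise
#' detection, LT2 modified D-max, heart-rate mapping, and five-zone
#' construction anchored at the test's VO2peak heart-rate landmarks. With
#' `config$lt2_scale_on = "power"`, the 95%/102% zone fractions are applied
#' to LT2 power first and then mapped to heart rate (the heart rates so
#' obtained replace the default direct scaling of LT2 heart rate).
#'
#' @param test a [step_test()].
#' @param config a [pipeline_config()].
#' @return A [zone_model()] with the threshold estimates attached as
#'   attribute `thresholds`.
#' @export
#' @examples
#' zone_model_from_test(generate_step_test(athlete_profile(), seed = 1))
zone_model_from_test <- function(test, config = pipeline_config()) {
  curve <- fit_lactate_curve(test)
  lt1 <- detect_lt1(test, curve, config)
  lt2 <- detect_lt2_mod_dmax(test, curve, lt1$power, config)
  hr50 <- test$hr_at_50pct_vo2peak
  hr100 <- test$hr_at_100pct_vo2peak
  zm <- if (config$lt2_scale_on == "hr") {
    build_zone_model(lt1$hr, lt2$hr, hr50, hr100, test$athlete_id, config)
  } else {
    p_max <- max(test$steps$power_w)
    t3_top <- power_to_hr(test, min(config$t4_lower_frac * lt2$power, p_max))
    t4_top <- power_to_hr(test, min(config$t4_upper_frac * lt2$power, p_max))
    stopifnot(t3_top > lt1$hr, t4_top < hr100)
    zone_model(c(hr50, (hr50 + lt1$hr) / 2, lt1$hr, t3_top, t4_top, hr100),
               athlete_id = test$athlete_id,
               landmarks = list(hr50 = hr50, lt1_hr = lt1$hr,
                                lt2_hr = lt2$hr, hr100 = hr100))
  }
  attr(zm, "thresholds") <- list(lt1 = lt1, lt2 = lt2,
                                 curve_coefficients = curve$coefficients)
  zm
}
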