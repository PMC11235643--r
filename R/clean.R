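#' Stroke-rate band filter
#'
#' Keeps records whose stroke rate lies inside the band (bounds inclusive,
#' default 14--50 spm). Very low stroke rates come from technical drills
#' and turning the boat; very high values are sensor artifacts.
#'
#' @param sr numeric vector of stroke rates (spm).
#' @param band numeric length 2, inclusive bounds.
#' @return Logical keep mask, same length as `sr`.
#' @export
#' @examples
#' filter_sr_band(c(10, 14, 20, 50, 51))
filter_sr_band <- function(sr, band = c(14, 50)) {
  is.finite(sr) & sr >= band[1] & sr <= band[2]
}

#' Trailing moving-average velocity smoothing
#'
#' Trailing (causal) mean over `window` samples (15 s at 1 Hz by default).
#' The first `window - 1` samples use the mean of all samples available so
#' far (expanding head), so the output has no leading missing values.
#'
#' @param v numeric velocity vector (m/s).
#' @param window window length in samples.
#' @param allow_short keep the expanding mean when `length(v) < window`
#'   instead of signalling an error.
#' @return Smoothed vector, same length as `v`.
#' @export
#' @examples
#' smooth_velocity(c(rep(0, 20), rep(1, 20)))
smooth_velocity <- function(v, window = 15L, allow_short = FALSE) {
  n <- length(v)
  if (n < window && !allow_short) {
    stop("stream shorter than the smoothing window (", window, " samples)",
         call. = FALSE)
  }
  if (n == 0L) return(numeric(0))
  cs <- cumsum(v)
  w <- min(window, n)
  lagged <- c(rep(0, w), cs[seq_len(n - w)])
  denom <- pmin(seq_len(n), window)
  (cs - lagged) / denom
}

#' Velocity band filter
#'
#' Keeps records whose smoothed velocity lies inside the band (bounds
#' inclusive, default 2.1--7.0 m/s), removing stationary-boat and
#' implausibly fast readings.
#'
#' @param v numeric vector of (smoothed) velocities (m/s).
#' @param band numeric length 2, inclusive bounds.
#' @return Logical keep mask.
#' @export
#' @examples
#' filter_velocity_band(c(2.0, 2.1, 5, 7.0, 7.1))
filter_velocity_band <- function(v, band = c(2.1, 7.0)) {
  is.finite(v) & v >= band[1] & v <= band[2]
}

#' Convert velocity to prognostic velocity
#'
#' Expresses boat velocity as a percentage of the senior world-best
#' velocity for the boat class and sex: `100 * velocity / world_best`.
#'
#' @param velocity numeric (m/s).
#' @param boat_class one of [boat_classes()].
#' @param sex `"M"` or `"F"`.
#' @param table world-best lookup, see [world_best_velocity()].
#' @return Prognostic velocity in percent.
#' @export
#' @examples
#' tab <- world_best_velocity()
#' to_prognostic(4.8, "1X", "M", tab)
to_prognostic <- function(velocity, boat_class, sex,
                          table = world_best_velocity()) {
  100 * velocity / prognostic_lookup(table, boat_class, sex)
}

#' Classify heart rate into training zones
#'
#' Assigns each heart rate to the unique zone interval of a
#' [zone_model()]. Intervals are upper-inclusive, T1 additionally includes
#' its lower bound. Heart rates below T1 are labelled `"below"` (removed
#' by the cascade, as sub-zone data carries no training-intensity
#' information); heart rates above the T5 ceiling are clamped into T5 by
#' default (supramaximal readings still reflect maximal-intensity work) or
#' labelled `"above"` when `above_t5 = "drop"`.
#'
#' @param hr numeric heart rates (bpm).
#' @param model a [zone_model()].
#' @param above_t5 `"clamp"` or `"drop"`.
#' @return Character vector over `"T1".."T5"`, `"below"`, `"above"`.
#' @export
#' @examples
#' zm <- build_zone_model(150, 180, 120, 200)
#' classify_zone(c(119, 120, 140, 150, 185, 201), zm)
classify_zone <- function(hr, model, above_t5 = c("clamp", "drop")) {
  stopifnot(inherits(model, "zone_model"))
  above_t5 <- match.arg(above_t5)
  b <- model$boundaries
  j <- findInterval(hr, b, left.open = TRUE)
  j[hr == b[1]] <- 1L  # T1 lower bound inclusive
  out <- rep(NA_character_, length(hr))
  inside <- j >= 1L & j <= 5L
  out[inside] <- paste0("T", j[inside])
  out[j == 0L] <- "below"
  out[j == 6L] <- if (above_t5 == "clamp") "T5" else "above"
  out
}

#' Gradient (rapid-change) filter
#'
#' Removes the record at time `t` when the stroke rate changed by at least
#' `grad_sr_delta` spm relative to the record 5 s prior and the smoothed
#' velocity changed by at least `grad_vel_delta` m/s relative to the record
#' 3 s prior (defaults; both lookbacks resolved by timestamp, not index).
#' A missing reference record — before the start, in a gap, or removed by
#' an earlier stage — makes that condition false, so with the default
#' `"and"` connective the point is kept. `"or"` removes the point when
#' either condition fires alone.
#'
#' @param time_s integer timestamps (s).
#' @param sr stroke rates (spm).
#' @param vel smoothed velocities (m/s).
#' @param config a [pipeline_config()].
#' @return Logical keep mask.
#' @export
#' @examples
#' gradient_filter(0:9, c(rep(16, 5), rep(32, 5)), c(rep(1, 5), rep(4, 5)))
gradient_filter <- function(time_s, sr, vel, config = pipeline_config()) {
  ref_sr <- match(time_s - config$grad_sr_lag, time_s)
  ref_v <- match(time_s - config$grad_vel_lag, time_s)
  cond_sr <- !is.na(ref_sr) & abs(sr - sr[ref_sr]) >= config$grad_sr_delta
  cond_v <- !is.na(ref_v) & abs(vel - vel[ref_v]) >= config$grad_vel_delta
  remove <- if (config$grad_connective == "and") cond_sr & cond_v else cond_sr | cond_v
  !remove
}

#' Minimum-run zone filter
#'
#' Removes every maximal run of identical zone labels shorter than
#' `min_run` points (default 15), discarding brief zone visits such as the
#' heart-rate lag at the start of a harder effort.
#'
#' @param labels character vector of zone labels.
#' @param min_run minimum run length to keep.
#' @return Logical keep mask.
#' @export
#' @examples
#' min_run_filter(rep(c("T1", "T2", "T1"), c(20, 5, 20)))
min_run_filter <- function(labels, min_run = 15L) {
  if (length(labels) == 0L) return(logical(0))
  r <- rle(labels)
  rep(r$lengths >= min_run, r$lengths)
}

#' Clean one session stream
#'
#' Applies the full filter cascade in order: stroke-rate band, 15 s
#' velocity smoothing, velocity band, prognostic-velocity conversion,
#' heart-rate zone classification (dropping below-T1 data), gradient
#' filter, minimum-run filter. Records per-stage removal counts and the
#' overall retention fraction.
#'
#' @param stream a [session_stream()].
#' @param model the athlete's [zone_model()].
#' @param world_best world-best velocity lookup ([world_best_velocity()]).
#' @param config a [pipeline_config()].
#' @param sex athlete sex for the prognostic lookup; defaults to the
#'   stream's `sex` attribute, else `"M"`.
#' @return A `clean_stream` tibble (`time_s`, `sr_spm`, `velocity_ms`,
#'   `velocity_smoothed`, `prognostic_velocity`, `hr_bpm`, `zone`) carrying
#'   the session metadata and a `retention` attribute: `raw`, `surviving`,
#'   `fraction`, and the named per-stage removal counts, which always sum
#'   to `raw - surviving`.
#' @export
#' @examples
#' prof <- athlete_profile()
#' zm <- zone_model_from_test(generate_step_test(prof, seed = 1))
#' s <- generate_session(prof, standard_template("steady", duration_scale = 0.2),
#'                       zm, seed = 2)
#' cs <- clean_session(s, zm)
#' attr(cs, "retention")$fraction
clean_session <- function(stream, model, world_best = world_best_velocity(),
                          config = pipeline_config(), sex = NULL) {
  stopifnot(inherits(stream, "session_stream"), inherits(model, "zone_model"))
  sex <- sex %||% attr(stream, "sex") %||% "M"
  boat_class <- attr(stream, "boat_class")
  n0 <- nrow(stream)
  stages <- c(sr_band = 0L, velocity_band = 0L, below_t1 = 0L,
              above_t5 = 0L, gradient = 0L, min_run = 0L)

  d <- tibble(time_s = stream$time_s, sr_spm = stream$sr_spm,
              velocity_ms = stream$velocity_ms, hr_bpm = stream$hr_bpm)

  keep <- filter_sr_band(d$sr_spm, config$sr_band)
  stages["sr_band"] <- sum(!keep)
  d <- d[keep, ]

  d$velocity_smoothed <- smooth_velocity(d$velocity_ms, config$smooth_window,
                                         allow_short = TRUE)
  keep <- filter_velocity_band(d$velocity_smoothed, config$vel_band)
  stages["velocity_band"] <- sum(!keep)
  d <- d[keep, ]

  d$prognostic_velocity <- to_prognostic(d$velocity_smoothed, boat_class,
                                         sex, world_best)
  d$zone <- classify_zone(d$hr_bpm, model, config$above_t5)
  stages["below_t1"] <- sum(d$zone == "below")
  stages["above_t5"] <- sum(d$zone == "above")
  d <- d[!d$zone %in% c("below", "above"), ]

  keep <- gradient_filter(d$time_s, d$sr_spm, d$velocity_smoothed, config)
  stages["gradient"] <- sum(!keep)
  d <- d[keep, ]

  keep <- min_run_filter(d$zone, config$min_run)
  stages["min_run"] <- sum(!keep)
  d <- d[keep, ]

  if (nrow(d) == 0L) {
    warning("empty session after cleaning: ", attr(stream, "session_id"),
            call. = FALSE)
  }
  structure(d,
            class = c("clean_stream", class(d)),
            athlete_id = attr(stream, "athlete_id"),
            date = attr(stream, "date"),
            boat_class = boat_class,
            sex = sex,
            session_id = attr(stream, "session_id"),
            truth = attr(stream, "truth"),
            retention = list(raw = n0, surviving = nrow(d),
                             fraction = nrow(d) / n0, stages = stages))
}

#' @export
print.clean_stream <- function(x, ...) {
  ret <- attr(x, "retention")
  cat(sprintf("<clean_stream> %s %s (%s): %d of %d records retained (%.1f%%)\n",
              attr(x, "athlete_id"), format(attr(x, "date")),
              attr(x, "boat_class"), ret$surviving, ret$raw,
              100 * ret$fraction))
  NextMethod()
}

#' Clean every session of a cohort
#'
#' Maps [clean_session()] over a [generate_cohort()] result (or any list of
#' streams plus named zone models), matching each stream to its athlete's
#' zone model.
#'
#' @param cohort a `rowing_cohort`, or a list of `session_stream`s.
#' @param zone_models named list of [zone_model()]s (required when `cohort`
#'   is a plain list).
#' @param world_best,config see [clean_session()].
#' @return List of `clean_stream`s. Sessions whose athlete has no zone
#'   model are skipped with a warning.
#' @export
clean_cohort <- function(cohort, zone_models = NULL,
                         world_best = world_best_velocity(),
                         config = pipeline_config()) {
  if (inherits(cohort, "rowing_cohort")) {
    zone_models <- zone_models %||% cohort$zone_models
    sessions <- cohort$sessions
  } else {
    sessions <- cohort
  }
  stopifnot(!is.null(zone_models))
  out <- list()
  for (s in sessions) {
    id <- attr(s, "athlete_id")
    if (is.null(zone_models[[id]])) {
      warning("no zone model for athlete ", id, "; session ",
              attr(s, "session_id"), " skipped", call. = FALSE)
      next
    }
    out[[length(out) + 1L]] <- clean_session(s, zone_models[[id]],
                                             world_best, config)
  }
  out
}
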