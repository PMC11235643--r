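#' Pool cleaned sessions into one record table
#'
#' Binds a list of `clean_stream`s into a single tibble with the session
#' metadata (`athlete_id`, `session_id`, `date`, `boat_class`) as columns.
#'
#' @param streams list of `clean_stream`s (see [clean_session()]).
#' @return A tibble.
#' @export
bind_clean_streams <- function(streams) {
  if (inherits(streams, "clean_stream")) streams <- list(streams)
  parts <- lapply(streams, function(s) {
    if (nrow(s) == 0L) return(NULL)
    tibble(
      athlete_id = attr(s, "athlete_id"),
      session_id = attr(s, "session_id"),
      date = attr(s, "date"),
      boat_class = attr(s, "boat_class"),
      time_s = s$time_s, sr_spm = s$sr_spm,
      velocity_smoothed = s$velocity_smoothed,
      prognostic_velocity = s$prognostic_velocity,
      hr_bpm = s$hr_bpm, zone = s$zone
    )
  })
  dplyr::bind_rows(parts)
}

#' Session-by-zone summary
#'
#' Arithmetic means of stroke rate and prognostic velocity per (athlete,
#' session, heart-rate zone). Zones with no surviving records in a session
#' are omitted.
#'
#' @param streams list of `clean_stream`s, or a pooled tibble from
#'   [bind_clean_streams()].
#' @return A `zone_summary` tibble: `athlete_id`, `session_id`, `zone`,
#'   `n`, `mean_sr`, `mean_prog_vel`.
#' @export
summarize_by_zone <- function(streams) {
  d <- if (is.data.frame(streams) && !inherits(streams, "clean_stream")) {
    streams
  } else {
    bind_clean_streams(streams)
  }
  out <- d |>
    dplyr::group_by(.data$athlete_id, .data$session_id, .data$zone) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_sr = mean(.data$sr_spm),
      mean_prog_vel = mean(.data$prognostic_velocity),
      .groups = "drop"
    ) |>
    dplyr::mutate(zone = factor(.data$zone, levels = paste0("T", 1:5)))
  class(out) <- c("zone_summary", class(out))
  out
}

#' Overlapping index between two samples
#'
#' The overlapping index eta-hat is the integral of the pointwise minimum
#' of two Gaussian-kernel density estimates evaluated on a common grid:
#' 0 means the distributions are completely separated, 1 that they are
#' identical. Bandwidths follow Silverman's rule (`stats::bw.nrd0`) per
#' sample; the grid spans the joint range extended by `kde_cut` bandwidths
#' on each side, and the integral is taken by the trapezoidal rule and
#' clipped to \[0, 1\].
#'
#' @param a,b numeric samples (each n >= 10, non-degenerate).
#' @param config a [pipeline_config()] (`kde_n_grid`, `kde_cut`).
#' @return eta-hat in \[0, 1\].
#' @export
#' @examples
#' set.seed(1)
#' overlap_index(rnorm(500), rnorm(500, 2))  # ~ 2 * pnorm(-1) = 0.317
overlap_index <- function(a, b, config = pipeline_config()) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 10L || length(b) < 10L) {
    stop("overlap_index needs at least 10 finite points per sample",
         call. = FALSE)
  }
  if (sd(a) == 0 || sd(b) == 0) {
    stop("degenerate (zero-variance) sample", call. = FALSE)
  }
  ha <- stats::bw.nrd0(a)
  hb <- stats::bw.nrd0(b)
  lo <- min(min(a) - config$kde_cut * ha, min(b) - config$kde_cut * hb)
  hi <- max(max(a) + config$kde_cut * ha, max(b) + config$kde_cut * hb)
  fa <- density(a, bw = ha, from = lo, to = hi, n = config$kde_n_grid)
  fb <- density(b, bw = hb, from = lo, to = hi, n = config$kde_n_grid)
  m <- pmin(fa$y, fb$y)
  dx <- diff(fa$x)
  eta <- sum((m[-1] + m[-length(m)]) / 2 * dx)
  min(max(eta, 0), 1)
}

#' Pairwise zone overlap matrix
#'
#' Computes the overlapping index between the zone-conditional
#' distributions of a variable, for every pair of heart-rate zones, from
#' pooled cleaned records.
#'
#' @param streams list of `clean_stream`s or a pooled tibble.
#' @param variable `"sr"` or `"prognostic_velocity"`.
#' @param config a [pipeline_config()].
#' @return A symmetric 5 x 5 matrix (rows/cols T1..T5) with unit diagonal;
#'   `NA` where a zone has fewer than 10 records.
#' @export
overlap_matrix <- function(streams, variable = c("sr", "prognostic_velocity"),
                           config = pipeline_config()) {
  variable <- match.arg(variable)
  d <- if (is.data.frame(streams) && !inherits(streams, "clean_stream")) {
    streams
  } else {
    bind_clean_streams(streams)
  }
  col <- if (variable == "sr") "sr_spm" else "prognostic_velocity"
  zones <- paste0("T", 1:5)
  samples <- lapply(zones, function(z) d[[col]][d$zone == z])
  m <- matrix(NA_real_, 5, 5, dimnames = list(zones, zones))
  diag(m) <- ifelse(vapply(samples, length, 0L) >= 10L, 1, NA_real_)
  for (i in 1:4) for (j in (i + 1):5) {
    if (length(samples[[i]]) >= 10L && length(samples[[j]]) >= 10L) {
      m[i, j] <- m[j, i] <- overlap_index(samples[[i]], samples[[j]], config)
    }
  }
  m
}

#' Mixed-effects zone contrasts
#'
#' Fits `response ~ zone + (1 | athlete_id)` by REML ([lmerTest::lmer()]),
#' extracts the fixed-effect zone means (estimated marginal means) and all
#' 10 pairwise zone differences with 95% confidence limits, raw p-values
#' (Satterthwaite degrees of freedom) and Benjamini-Hochberg adjusted
#' p-values. With a single athlete the random intercept is unidentifiable:
#' the model falls back to a fixed-effects `lm` with a warning.
#'
#' @param summary a `zone_summary` (from [summarize_by_zone()] or
#'   [generate_zone_summary()]).
#' @param response `"mean_sr"` or `"mean_prog_vel"`.
#' @param config a [pipeline_config()] (`fdr_method`).
#' @return A `zone_contrasts` list: `means` (tibble: zone, emmean, SE, df,
#'   CLs), `contrasts` (tibble: contrast, estimate, SE, CLs, p_raw, p_adj),
#'   `ranef` (`athlete_sd`, `resid_sd`), `model`.
#' @export
#' @examples
#' zs <- generate_zone_summary(6, 5, seed = 1)
#' fit_zone_contrasts(zs)
fit_zone_contrasts <- function(summary,
                               response = c("mean_sr", "mean_prog_vel"),
                               config = pipeline_config()) {
  response <- match.arg(response)
  d <- as.data.frame(summary)
  d$zone <- factor(d$zone, levels = paste0("T", 1:5))
  d <- d[!is.na(d[[response]]), ]
  stopifnot(nlevels(droplevels(d$zone)) >= 2L)
  one_athlete <- length(unique(d$athlete_id)) < 2L
  adj <- if (toupper(config$fdr_method) %in% c("BH", "FDR")) "fdr" else config$fdr_method

  if (one_athlete) {
    warning("single athlete: random intercept unidentifiable, ",
            "falling back to fixed-effects lm", call. = FALSE)
    fit <- lm(stats::reformulate("zone", response), data = d)
    emm <- emmeans::emmeans(fit, "zone")
    ranef <- list(athlete_sd = NA_real_, resid_sd = sigma(fit))
  } else {
    fml <- stats::as.formula(paste(response, "~ zone + (1 | athlete_id)"))
    fit <- lmerTest::lmer(fml, data = d, REML = TRUE)
    emm <- emmeans::emmeans(fit, "zone", lmer.df = "satterthwaite")
    vc <- as.data.frame(lme4::VarCorr(fit))
    ranef <- list(
      athlete_sd = vc$sdcor[vc$grp == "athlete_id"],
      resid_sd = vc$sdcor[vc$grp == "Residual"]
    )
  }
  prs <- emmeans::contrast(emm, method = "pairwise", adjust = "none")
  raw <- as.data.frame(prs)
  ci <- as.data.frame(stats::confint(prs, level = 0.95))
  contrasts <- tibble(
    contrast = as.character(raw$contrast),
    estimate = raw$estimate, SE = raw$SE, df = raw$df,
    lower_cl = ci$lower.CL, upper_cl = ci$upper.CL,
    p_raw = raw$p.value,
    p_adj = stats::p.adjust(raw$p.value, method = if (adj == "fdr") "BH" else adj)
  )
  means <- as_tibble(as.data.frame(emm))
  structure(list(means = means, contrasts = contrasts, ranef = ranef,
                 response = response, model = fit),
            class = "zone_contrasts")
}

#' @export
print.zone_contrasts <- function(x, ...) {
  cat(sprintf("<zone_contrasts> response: %s (REML, random athlete intercept)\n",
              x$response))
  cat(sprintf("  athlete SD = %s, residual SD = %.3f\n",
              if (is.na(x$ranef$athlete_sd)) "NA (single athlete)"
              else sprintf("%.3f", x$ranef$athlete_sd),
              x$ranef$resid_sd))
  cat("Zone means:\n"); print(as.data.frame(x$means), digits = 4)
  cat("Pairwise contrasts (FDR-adjusted p):\n")
  print(as.data.frame(x$contrasts), digits = 4)
  invisible(x)
}

#' Stroke-rate bin summary
#'
#' Means of stroke rate and prognostic velocity per (athlete, session,
#' stroke-rate bin), after restricting to one boat class (the single scull
#' by default, where stroke rate and velocity are the athlete's own). Bins
#' are 14-18, 19-21, 22-24, ..., 43-45, 46-50 spm, closed on both printed
#' ends; stroke rate is rounded to the nearest spm before lookup.
#'
#' @param streams list of `clean_stream`s or a pooled tibble.
#' @param boat_class boat class to keep (must be one of [boat_classes()]).
#' @return Tibble: `athlete_id`, `session_id`, `date`, `sr_bin`, `n`,
#'   `mean_sr`, `mean_prog_vel`.
#' @export
sr_bin_summary <- function(streams, boat_class = "1X") {
  if (!boat_class %in% boat_classes()) {
    stop("unknown boat class: ", boat_class, call. = FALSE)
  }
  d <- if (is.data.frame(streams) && !inherits(streams, "clean_stream")) {
    streams
  } else {
    bind_clean_streams(streams)
  }
  d <- d[d$boat_class == boat_class, ]
  if (nrow(d) == 0L) return(tibble())
  d$sr_bin <- sr_bin_label(d$sr_spm)
  d |>
    dplyr::filter(!is.na(.data$sr_bin)) |>
    dplyr::group_by(.data$athlete_id, .data$session_id, .data$date,
                    .data$sr_bin) |>
    dplyr::summarise(n = dplyr::n(), mean_sr = mean(.data$sr_spm),
                     mean_prog_vel = mean(.data$prognostic_velocity),
                     .groups = "drop")
}

#' Stroke-rate bin labels
#'
#' Maps stroke rates to the standard bins (14-18, 19-21, ..., 46-50 spm)
#' by rounding to the nearest spm first.
#'
#' @param sr numeric stroke rates (spm).
#' @return Ordered factor of bin labels; `NA` outside 14--50 spm.
#' @export
#' @examples
#' sr_bin_label(c(18.4, 19.0, 21.0, 50))
sr_bin_label <- function(sr) {
  lows <- c(14, 19, 22, 25, 28, 31, 34, 37, 40, 43, 46)
  highs <- c(18, 21, 24, 27, 30, 33, 36, 39, 42, 45, 50)
  labels <- paste0(lows, "-", highs)
  r <- round(sr)
  idx <- findInterval(r, lows)
  idx[r < lows[1] | r > highs[length(highs)]] <- NA
  factor(labels[idx], levels = labels, ordered = TRUE)
}

#' Pearson correlation with magnitude label
#'
#' Pearson product-moment correlation with a two-sided p-value and the
#' conventional magnitude descriptor (|r| < 0.1 trivial; 0.1-0.3 small;
#' 0.3-0.5 moderate; 0.5-0.7 large; 0.7-0.9 very large; 0.9-1 nearly
#' perfect; 1 perfect; boundary values take the higher category).
#' Optionally also computed within groups (per athlete).
#'
#' @param x,y paired numeric vectors (n >= 3; non-degenerate).
#' @param by optional grouping vector for per-group correlations.
#' @return A `correlation_result` list: `r`, `p`, `n`, `magnitude`, and
#'   `per_group` (tibble or `NULL`).
#' @export
#' @examples
#' correlate(1:10, 2 * (1:10) + 1)
correlate <- function(x, y, by = NULL) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (!is.null(by)) by <- by[ok]
  if (length(x) < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  ct <- cor.test(x, y, method = "pearson")
  per_group <- NULL
  if (!is.null(by)) {
    per_group <- dplyr::bind_rows(lapply(split(seq_along(x), by), function(i) {
      if (length(i) < 3L || sd(x[i]) == 0 || sd(y[i]) == 0) return(NULL)
      r <- stats::cor(x[i], y[i])
      tibble(group = as.character(by[i[1]]), n = length(i), r = r,
             magnitude = correlation_magnitude(r))
    }))
  }
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
                 magnitude = correlation_magnitude(unname(ct$estimate)),
                 per_group = per_group),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> r = %.3f (%s), p = %.3g, n = %d\n",
              x$r, x$magnitude, x$p, x$n))
  if (!is.null(x$per_group) && nrow(x$per_group)) {
    cat(sprintf("  per-group r: %.2f to %.2f across %d groups\n",
                min(x$per_group$r), max(x$per_group$r), nrow(x$per_group)))
  }
  invisible(x)
}

#' Correlation magnitude descriptor
#'
#' @param r correlation coefficient(s).
#' @return Character label(s): trivial, small, moderate, large, very
#'   large, nearly perfect, perfect. Boundary values take the higher
#'   category (0.5 is "large").
#' @export
#' @examples
#' correlation_magnitude(c(0.05, 0.5, -0.72, 1))
correlation_magnitude <- function(r) {
  labels <- c("trivial", "small", "moderate", "large", "very large",
              "nearly perfect", "perfect")
  # tiny tolerance so a floating-point r of 1 - eps still reads "perfect"
  a <- pmin(abs(r), 1) + 1e-9
  labels[findInterval(a, c(0.1, 0.3, 0.5, 0.7, 0.9, 1)) + 1L]
}

#' Progression of prognostic velocity at 20 spm
#'
#' Restricts single-scull records to the 19--21 spm stroke-rate window,
#' averages prognostic velocity per session, and correlates the session
#' means against time (days since the first session), overall and per
#' athlete. A flat correlation indicates no measurable on-water progression
#' at the benchmark stroke rate.
#'
#' @param streams list of `clean_stream`s or a pooled tibble.
#' @param boat_class boat class to keep (default `"1X"`).
#' @param config a [pipeline_config()] (`sr20_window`).
#' @return A `correlation_result` with the per-session table attached as
#'   attribute `sessions`.
#' @export
progression_at_sr20 <- function(streams, boat_class = "1X",
                                config = pipeline_config()) {
  d <- if (is.data.frame(streams) && !inherits(streams, "clean_stream")) {
    streams
  } else {
    bind_clean_streams(streams)
  }
  w <- config$sr20_window
  d <- d[d$boat_class == boat_class, ]
  d <- d[round(d$sr_spm) >= w[1] & round(d$sr_spm) <= w[2], ]
  if (nrow(d) == 0L) {
    warning("no records in the ", w[1], "-", w[2], " spm window", call. = FALSE)
    return(NULL)
  }
  per_session <- d |>
    dplyr::group_by(.data$athlete_id, .data$session_id, .data$date) |>
    dplyr::summarise(mean_prog_vel = mean(.data$prognostic_velocity),
                     n = dplyr::n(), .groups = "drop")
  if (length(unique(per_session$date)) < 2L) {
    stop("sessions span a single date: progression undefined", call. = FALSE)
  }
  per_session$day <- as.numeric(per_session$date - min(per_session$date))
  res <- correlate(per_session$day, per_session$mean_prog_vel,
                   by = per_session$athlete_id)
  attr(res, "sessions") <- per_session
  res
}

#' Retention report across sessions
#'
#' Aggregates the per-stage removal accounting of cleaned sessions. Counts
#' are conserved: the stage removals sum exactly to raw minus surviving,
#' per session and in total.
#'
#' @param streams list of `clean_stream`s.
#' @return List: `overall_fraction`, `raw`, `surviving`, `stages` (named
#'   total removals per filter stage), `per_session` tibble.
#' @export
retention_report <- function(streams) {
  if (inherits(streams, "clean_stream")) streams <- list(streams)
  rets <- lapply(streams, attr, "retention")
  stopifnot(length(rets) > 0L, !vapply(rets, is.null, TRUE))
  stages <- Reduce(`+`, lapply(rets, `[[`, "stages"))
  raw <- sum(vapply(rets, `[[`, 0, "raw"))
  surviving <- sum(vapply(rets, `[[`, 0, "surviving"))
  per_session <- dplyr::bind_rows(lapply(seq_along(streams), function(i) {
    r <- rets[[i]]
    tibble(session_id = attr(streams[[i]], "session_id") %||% as.character(i),
           raw = r$raw, surviving = r$surviving, fraction = r$fraction)
  }))
  list(overall_fraction = surviving / raw, raw = raw, surviving = surviving,
       stages = stages, per_session = per_session)
}
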