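#' Pipeline configuration
#'
#' Collects every tunable constant of the cleaning cascade, the zone model
#' and the statistical analyses in one list. Defaults are the values used
#' throughout the package documentation: a 14--50 spm stroke-rate band, a
#' 15 s trailing moving average on velocity, a 2.1--7.0 m s^-1 velocity
#' band, a gradient filter (>= 1.5 spm change versus 5 s prior AND
#' >= 0.2 m s^-1 change versus 3 s prior), and a 15-point minimum run per
#' heart-rate zone.
#'
#' @param sr_band numeric length 2; inclusive stroke-rate band in spm.
#' @param vel_band numeric length 2; inclusive smoothed-velocity band in
#'   m s^-1.
#' @param smooth_window integer; trailing moving-average window in samples
#'   (= seconds at 1 Hz).
#' @param grad_sr_delta,grad_sr_lag gradient filter: stroke-rate change
#'   threshold (spm) and lookback (s).
#' @param grad_vel_delta,grad_vel_lag gradient filter: smoothed-velocity
#'   change threshold (m s^-1) and lookback (s).
#' @param grad_connective `"and"` (both conditions must fire, the default
#'   reading) or `"or"` (either condition alone removes the point).
#' @param min_run integer; minimum number of consecutive points in a zone
#'   for those points to be kept.
#' @param above_t5 `"clamp"` (heart rates above the T5 ceiling are kept and
#'   assigned to T5) or `"drop"`.
#' @param lt1_rise mmol L^-1 rise over baseline lactate defining LT1.
#' @param lt1_baseline `"fitted"` (curve value at the first step power) or
#'   `"observed"` (measured first-step lactate).
#' @param dmax_grid grid spacing in W for the threshold searches.
#' @param t4_lower_frac,t4_upper_frac the fractions of LT2 bounding zone T4
#'   (defaults 0.95 and 1.02).
#' @param lt2_scale_on `"hr"` (apply the T4 fractions to the heart rate at
#'   LT2) or `"power"` (apply them to LT2 power, then map to heart rate).
#' @param kde_n_grid,kde_cut overlap index: number of grid points and the
#'   bandwidth multiple by which the grid extends past each sample range.
#' @param fdr_method multiplicity adjustment for pairwise zone contrasts
#'   (passed to [emmeans::emmeans()]; `"BH"`/`"fdr"` = Benjamini-Hochberg).
#' @param sr20_window numeric length 2; stroke-rate window (spm) defining
#'   the "20 spm" progression subset.
#'
#' @return A named list with class `rowzone_config`.
#' @export
#' @examples
#' cfg <- pipeline_config(grad_connective = "or")
#' cfg$sr_band
pipeline_config <- function(sr_band = c(14, 50),
                            vel_band = c(2.1, 7.0),
                            smooth_window = 15L,
                            grad_sr_delta = 1.5,
                            grad_sr_lag = 5L,
                            grad_vel_delta = 0.2,
                            grad_vel_lag = 3L,
                            grad_connective = c("and", "or"),
                            min_run = 15L,
                            above_t5 = c("clamp", "drop"),
                            lt1_rise = 0.4,
                            lt1_baseline = c("fitted", "observed"),
                            dmax_grid = 0.1,
                            t4_lower_frac = 0.95,
                            t4_upper_frac = 1.02,
                            lt2_scale_on = c("hr", "power"),
                            kde_n_grid = 1024L,
                            kde_cut = 3,
                            fdr_method = "BH",
                            sr20_window = c(19, 21)) {
  stopifnot(
    length(sr_band) == 2L, sr_band[1] < sr_band[2],
    length(vel_band) == 2L, vel_band[1] < vel_band[2],
    smooth_window >= 1L, grad_sr_delta > 0, grad_vel_delta > 0,
    grad_sr_lag > 0, grad_vel_lag > 0, min_run >= 1L,
    lt1_rise > 0, dmax_grid > 0,
    t4_lower_frac > 0, t4_lower_frac < 1, t4_upper_frac > 1,
    kde_n_grid >= 64L, kde_cut > 0
  )
  cfg <- list(
    sr_band = as.numeric(sr_band),
    vel_band = as.numeric(vel_band),
    smooth_window = as.integer(smooth_window),
    grad_sr_delta = grad_sr_delta,
    grad_sr_lag = as.integer(grad_sr_lag),
    grad_vel_delta = grad_vel_delta,
    grad_vel_lag = as.integer(grad_vel_lag),
    grad_connective = match.arg(grad_connective),
    min_run = as.integer(min_run),
    above_t5 = match.arg(above_t5),
    lt1_rise = lt1_rise,
    lt1_baseline = match.arg(lt1_baseline),
    dmax_grid = dmax_grid,
    t4_lower_frac = t4_lower_frac,
    t4_upper_frac = t4_upper_frac,
    lt2_scale_on = match.arg(lt2_scale_on),
    kde_n_grid = as.integer(kde_n_grid),
    kde_cut = kde_cut,
    fdr_method = fdr_method,
    sr20_window = as.numeric(sr20_window)
  )
  class(cfg) <- "rowzone_config"
  cfg
}

#' @export
print.rowzone_config <- function(x, ...) {
  cat("<rowzone_config>\n")
  cat(sprintf("  SR band: [%g, %g] spm; velocity band: [%g, %g] m/s; smoothing: %d s\n",
              x$sr_band[1], x$sr_band[2], x$vel_band[1], x$vel_band[2],
              x$smooth_window))
  cat(sprintf("  gradient: |dSR| >= %g spm over %d s %s |dv| >= %g m/s over %d s\n",
              x$grad_sr_delta, x$grad_sr_lag, toupper(x$grad_connective),
              x$grad_vel_delta, x$grad_vel_lag))
  cat(sprintf("  min run: %d points; above-T5 policy: %s\n", x$min_run, x$above_t5))
  cat(sprintf("  LT1 rise: %g mmol/L (%s baseline); D-max grid: %g W; T4 = [%g, %g] x LT2 (%s)\n",
              x$lt1_rise, x$lt1_baseline, x$dmax_grid,
              x$t4_lower_frac, x$t4_upper_frac, x$lt2_scale_on))
  invisible(x)
}
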