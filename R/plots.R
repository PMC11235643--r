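#' Boxplot of a variable by heart-rate zone
#'
#' The distribution of stroke rate or prognostic velocity across zones
#' T1..T5 of pooled cleaned records (median, interquartile range, 1.5 IQR
#' whiskers).
#'
#' @param streams list of `clean_stream`s or a pooled tibble.
#' @param variable `"sr"` or `"prognostic_velocity"`.
#' @return A ggplot object.
#' @export
plot_zone_distributions <- function(streams,
                                    variable = c("sr", "prognostic_velocity")) {
  variable <- match.arg(variable)
  d <- if (is.data.frame(streams) && !inherits(streams, "clean_stream")) {
    streams
  } else {
    bind_clean_streams(streams)
  }
  col <- if (variable == "sr") "sr_spm" else "prognostic_velocity"
  lab <- if (variable == "sr") "Stroke rate (spm)" else "Prognostic velocity (%)"
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$zone, paste0("T", 1:5)),
                                  y = .data[[col]])) +
    ggplot2::geom_boxplot(outlier.alpha = 0.15) +
    ggplot2::labs(x = "Heart-rate zone", y = lab) +
    ggplot2::theme_minimal()
}

#' Scatter of session-bin stroke rate against prognostic velocity
#'
#' One point per (athlete, session, stroke-rate bin) mean, with a grey
#' least-squares line per athlete and the pooled line in bold.
#'
#' @param bins output of [sr_bin_summary()].
#' @return A ggplot object.
#' @export
plot_sr_velocity <- function(bins) {
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$mean_sr, y = .data$mean_prog_vel)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_smooth(ggplot2::aes(group = .data$athlete_id),
                         method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey60", linewidth = 0.4) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "black", linewidth = 1.1) +
    ggplot2::labs(x = "Stroke rate (spm)", y = "Prognostic velocity (%)") +
    ggplot2::theme_minimal()
}

#' Progression of prognostic velocity at 20 spm over time
#'
#' @param progression a [progression_at_sr20()] result.
#' @return A ggplot object.
#' @export
plot_progression <- function(progression) {
  d <- attr(progression, "sessions")
  stopifnot(!is.null(d))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$day, y = .data$mean_prog_vel)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.9) +
    ggplot2::geom_smooth(ggplot2::aes(group = .data$athlete_id),
                         method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey60", linewidth = 0.4) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "black", linewidth = 1.1) +
    ggplot2::labs(x = "Day of observation period",
                  y = "Prognostic velocity at 20 spm (%)") +
    ggplot2::theme_minimal()
}
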