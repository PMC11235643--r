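.rowzone_env <- new.env(parent = emptyenv())

#' World-best velocity lookup
#'
#' Senior world-best boat velocities (m/s) per boat class and sex, the
#' denominator of prognostic velocity. The packaged defaults approximate
#' public 2000 m world-best times; for serious use supply the current
#' official table via [read_world_best()].
#'
#' @return Tibble: `boat_class`, `sex`, `velocity_ms`.
#' @export
#' @examples
#' world_best_velocity()
world_best_velocity <- function() {
  if (is.null(.rowzone_env$world_best)) {
    path <- system.file("extdata", "world_best_velocity.csv",
                        package = "rowzone", mustWork = TRUE)
    .rowzone_env$world_best <- read_world_best(path)
  }
  .rowzone_env$world_best
}

#' Read a world-best velocity table
#'
#' @param path CSV with columns `boat_class`, `sex`, `velocity_ms`; all
#'   velocities must lie in (4, 7) m/s.
#' @return Tibble usable wherever a `world_best` table is accepted.
#' @export
read_world_best <- function(path) {
  d <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  stopifnot(all(c("boat_class", "sex", "velocity_ms") %in% names(d)),
            all(d$velocity_ms > 4 & d$velocity_ms < 7),
            all(d$boat_class %in% boat_classes()),
            all(d$sex %in% c("M", "F")))
  d
}

prognostic_lookup <- function(table, boat_class, sex) {
  i <- which(table$boat_class == boat_class & table$sex == sex)
  if (length(i) != 1L) {
    stop("no world-best velocity for boat class ", boat_class,
         ", sex ", sex, call. = FALSE)
  }
  table$velocity_ms[i]
}

#' Write / read a session stream
#'
#' Sessions are stored as plain CSV (`time_s`, `sr_spm`, `velocity_ms`,
#' `hr_bpm`) with a YAML metadata sidecar (`<stem>.meta.yaml`: athlete,
#' date, boat class, sex) and, when present, a ground-truth sidecar
#' (`<stem>.truth.csv`). Columns are matched by name, so reordered headers
#' parse identically; rows with non-numeric values are skipped with a
#' warning.
#'
#' @param stream a [session_stream()].
#' @param path CSV path (the sidecar paths are derived from it).
#' @return `write_session` returns the main path invisibly; `read_session`
#'   returns a `session_stream`.
#' @export
write_session <- function(stream, path) {
  stopifnot(inherits(stream, "session_stream"))
  write.csv(as.data.frame(stream)[, c("time_s", "sr_spm", "velocity_ms", "hr_bpm")],
            path, row.names = FALSE)
  meta <- list(athlete_id = attr(stream, "athlete_id"),
               date = format(attr(stream, "date")),
               boat_class = attr(stream, "boat_class"),
               sex = attr(stream, "sex"),
               session_id = attr(stream, "session_id"))
  yaml::write_yaml(meta, sidecar(path, "meta.yaml"))
  truth <- attr(stream, "truth")
  if (!is.null(truth)) {
    write.csv(as.data.frame(truth), sidecar(path, "truth.csv"), row.names = FALSE)
  }
  invisible(path)
}

sidecar <- function(path, ext) {
  paste0(sub("\\.csv$", "", path), ".", ext)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("time_s", "sr_spm", "velocity_ms", "hr_bpm")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(raw) == 0L) stop("empty session file: ", path, call. = FALSE)
  num <- as_tibble(lapply(raw[required], function(x) suppressWarnings(as.numeric(x))))
  bad <- !stats::complete.cases(num)
  if (any(bad)) {
    warning(sum(bad), " malformed row(s) skipped in ", path, call. = FALSE)
    num <- num[!bad, ]
  }
  meta_path <- sidecar(path, "meta.yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  truth_path <- sidecar(path, "truth.csv")
  truth <- if (file.exists(truth_path)) as_tibble(read.csv(truth_path)) else NULL
  session_stream(num,
                 athlete_id = meta$athlete_id %||% "unknown",
                 date = meta$date %||% Sys.Date(),
                 boat_class = meta$boat_class %||% "1X",
                 sex = meta$sex %||% "M",
                 truth = truth,
                 session_id = meta$session_id)
}

#' Write / read a step test
#'
#' Step tests are stored as CSV (`step`, `power_w`, `lactate_mmol`,
#' `hr_bpm`) preceded by commented header lines carrying the VO2peak
#' landmarks.
#'
#' @param test a [step_test()].
#' @param path CSV path.
#' @return `write_step_test` returns the path invisibly; `read_step_test`
#'   returns a `step_test`.
#' @export
write_step_test <- function(test, path) {
  stopifnot(inherits(test, "step_test"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# athlete_id: ", test$athlete_id),
    paste0("# vo2peak: ", format(test$vo2peak, digits = 15)),
    paste0("# hr_at_50pct_vo2peak: ", format(test$hr_at_50pct_vo2peak, digits = 15)),
    paste0("# hr_at_100pct_vo2peak: ", format(test$hr_at_100pct_vo2peak, digits = 15))
  ), con)
  utils::write.table(as.data.frame(test$steps), con, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_step_test
#' @export
read_step_test <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(m)) stop("step-test header missing ", key, call. = FALSE)
    sub(paste0("^# ", key, ":\\s*"), "", m[1])
  }
  d <- read.csv(text = lines[!grepl("^#", lines)])
  step_test(d,
            vo2peak = as.numeric(get("vo2peak")),
            hr_at_50pct_vo2peak = as.numeric(get("hr_at_50pct_vo2peak")),
            hr_at_100pct_vo2peak = as.numeric(get("hr_at_100pct_vo2peak")),
            athlete_id = get("athlete_id"))
}

#' Write / read a zone model
#'
#' Zone models are stored as small YAML documents: athlete id, the six
#' zone boundaries, and the source landmarks.
#'
#' @param model a [zone_model()].
#' @param path YAML path.
#' @return `write_zone_model` returns the path invisibly; `read_zone_model`
#'   returns a `zone_model`.
#' @export
write_zone_model <- function(model, path) {
  stopifnot(inherits(model, "zone_model"))
  yaml::write_yaml(list(athlete_id = model$athlete_id,
                        boundaries = model$boundaries,
                        landmarks = model$landmarks), path)
  invisible(path)
}

#' @rdname write_zone_model
#' @export
read_zone_model <- function(path) {
  y <- yaml::read_yaml(path)
  zone_model(unlist(y$boundaries), athlete_id = y$athlete_id,
             landmarks = y$landmarks)
}

#' Run the full analysis pipeline
#'
#' Cleans every session against its athlete's zone model, then computes the
#' standard outputs: session-by-zone summary, pairwise zone overlap
#' matrices (stroke rate and prognostic velocity), mixed-model zone
#' contrasts for both responses, the single-scull stroke-rate/velocity
#' correlation, the 20 spm progression, and the retention report. All
#' tables are written as CSV under `out_dir` together with a JSON run
#' manifest (inputs, configuration hash, record counts, output list).
#' Identical inputs, configuration and seed yield identical output tables.
#'
#' @param sessions list of [session_stream()]s, or a [generate_cohort()]
#'   result (which also supplies the zone models).
#' @param zone_models named list of [zone_model()]s per athlete id.
#' @param out_dir output directory (created if needed).
#' @param world_best world-best velocity lookup.
#' @param config a [pipeline_config()].
#' @param seed optional integer recorded in the manifest (and set before
#'   any stochastic step; the pipeline itself is deterministic).
#' @return The manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(sessions, zone_models = NULL, out_dir,
                         world_best = world_best_velocity(),
                         config = pipeline_config(), seed = NULL) {
  if (inherits(sessions, "rowing_cohort")) {
    zone_models <- zone_models %||% sessions$zone_models
    sessions <- sessions$sessions
  }
  stopifnot(!is.null(zone_models), length(sessions) > 0L)
  if (!is.null(seed)) set.seed(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(obj, name) {
    p <- file.path(out_dir, name)
    write.csv(as.data.frame(obj), p, row.names = FALSE)
    outputs <<- c(outputs, p)
    p
  }

  clean <- clean_cohort(sessions, zone_models, world_best, config)
  pooled <- bind_clean_streams(clean)
  zs <- summarize_by_zone(pooled)
  emit(zs, "zone_summary.csv")

  for (v in c("sr", "prognostic_velocity")) {
    m <- overlap_matrix(pooled, v, config)
    emit(cbind(zone = rownames(m), as.data.frame(m)),
         paste0("overlap_", v, ".csv"))
  }
  for (resp in c("mean_sr", "mean_prog_vel")) {
    zc <- try(fit_zone_contrasts(zs, resp, config), silent = TRUE)
    if (!inherits(zc, "try-error")) {
      emit(zc$means, paste0("zone_means_", resp, ".csv"))
      emit(zc$contrasts, paste0("zone_contrasts_", resp, ".csv"))
    }
  }

  bins <- sr_bin_summary(pooled, "1X")
  if (nrow(bins)) {
    emit(bins, "sr_bins_1X.csv")
    cr <- try(correlate(bins$mean_sr, bins$mean_prog_vel, by = bins$athlete_id),
              silent = TRUE)
    if (!inherits(cr, "try-error")) {
      emit(tibble(r = cr$r, p = cr$p, n = cr$n, magnitude = cr$magnitude),
           "sr_velocity_correlation.csv")
    }
  }
  prog <- try(suppressWarnings(progression_at_sr20(pooled, "1X", config)),
              silent = TRUE)
  if (!inherits(prog, "try-error") && !is.null(prog)) {
    emit(tibble(r = prog$r, p = prog$p, n = prog$n, magnitude = prog$magnitude),
         "progression_sr20.csv")
  }

  ret <- retention_report(clean)
  emit(ret$per_session, "retention_per_session.csv")

  manifest <- list(
    created = format(Sys.time(), tz = "UTC"),
    seed = seed,
    config_hash = rlang::hash(config),
    n_sessions_in = length(sessions),
    n_sessions_cleaned = length(clean),
    counts = list(raw = ret$raw, surviving = ret$surviving,
                  stages = as.list(ret$stages),
                  overall_fraction = ret$overall_fraction),
    inputs = vapply(sessions, function(s) attr(s, "session_id"), ""),
    outputs = basename(outputs)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
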