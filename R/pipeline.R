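#' Run the full sEMG analysis pipeline
#'
#' Orchestrates one reproducible run: load (or synthesize) a session,
#' bandpass-condition it, extract envelope and median-frequency series,
#' detect and fuse precursor events, match them to annotated FOG onsets,
#' evaluate, and run the precursor-vs-normal state comparison. Every
#' artifact is stamped with the MD5 of the resolved configuration and the
#' seed; a failing stage removes any partial outputs.
#'
#' @param config A configuration list or the path to a YAML file with the
#'   same structure. Recognized keys (all optional unless noted):
#'   `input$recording` / `input$annotations` (CSV paths) or
#'   `input$synthetic` ([session_spec()] fields, with `episodes` as a list
#'   of [fog_episode()] field lists); `filter` ([filter_spec()] fields);
#'   `features` (`window_s`, `step_s`); `mdf` (`window_s`, `step_s`);
#'   `detector` ([detector_config()] fields); `fuse` (`min_channels`);
#'   `comparison` (`unit`); `seed`; `out_dir` (required).
#' @param out_dir Output directory (overrides `config$out_dir`).
#' @return Invisibly, a list with the in-memory results (`recording`,
#'   `filtered`, `envelope`, `mdf`, `events`, `report`, `comparison`) and
#'   the written `paths`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) abort("an output directory is required")
  seed <- as.integer(config$seed %||% 1L)

  # resolve and validate every stage configuration up front, before any
  # output is written, so a bad config fails with no partial artifacts
  fspec <- do.call(filter_spec, config$filter %||% list())
  dcfg <- do.call(detector_config, config$detector %||% list())
  feat <- utils::modifyList(list(window_s = 0.2, step_s = 0.01),
                            config$features %||% list())
  if (feat$step_s > feat$window_s) {
    abort("config error (features): step_s must not exceed window_s")
  }
  mdfc <- utils::modifyList(list(window_s = 1, step_s = 0.05),
                            config$mdf %||% list())
  min_channels <- (config$fuse %||% list())$min_channels %||% 2
  unit <- (config$comparison %||% list())$unit %||% "window"
  has_synth <- !is.null(config$input$synthetic)
  has_files <- !is.null(config$input$recording)
  if (!has_synth && !has_files) {
    abort("config error (input): need input$recording or input$synthetic")
  }
  if (has_files) {
    for (p in c(config$input$recording, config$input$annotations)) {
      if (!file.exists(p)) abort(paste0("config error (input): missing ", p))
    }
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  logf <- file.path(out_dir, "run.log")
  log_line <- function(stage, msg) {
    cat(sprintf("%s [%s] %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%OS3"),
                stage, msg), file = logf, append = TRUE)
  }
  emit <- function(path) written <<- c(written, path)

  run <- function() {
    set.seed(seed)
    cfg_path <- file.path(out_dir, "config.json")
    jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    emit(cfg_path)
    cfg_md5 <- unname(tools::md5sum(cfg_path))
    stamp <- list(config_md5 = cfg_md5, seed = seed)

    log_line("input", "loading session")
    if (has_synth) {
      sargs <- config$input$synthetic
      sargs$episodes <- lapply(sargs$episodes %||% list(), function(e) {
        do.call(fog_episode, e)
      })
      if (!is.null(sargs$channels)) {
        sargs$channels <- do.call(channel_meta, sargs$channels)
      }
      ses <- generate_session(do.call(session_spec, sargs))
      rec <- ses$recording
      track <- ses$annotations
    } else {
      rec <- read_recording(config$input$recording)
      track <- if (!is.null(config$input$annotations)) {
        read_annotations(config$input$annotations)
      } else NULL
    }

    log_line("preprocess", sprintf("bandpass %g-%g Hz order %d (%s)",
                                   fspec$low_hz, fspec$high_hz, fspec$order,
                                   fspec$mode))
    filt <- bandpass(rec, fspec)
    p <- file.path(out_dir, "filtered.csv")
    write_recording(filt, p)
    emit(p)

    log_line("features", sprintf("window %g s, step %g s",
                                 feat$window_s, feat$step_s))
    env <- sliding_features(filt, feat$window_s, feat$step_s)
    p <- file.path(out_dir, "envelope.csv")
    wide <- tidyr::pivot_wider(
      tibble::as_tibble(env), names_from = "channel",
      values_from = c("rms_mv", "mav_mv", "ptp_mv"), names_glue =
        "{channel}_{.value}")
    readr::write_csv(wide, p, progress = FALSE)
    emit(p)

    log_line("fatigue", sprintf("MDF window %g s, step %g s",
                                mdfc$window_s, mdfc$step_s))
    mdf <- mdf_series(filt, mdfc$window_s, mdfc$step_s)
    p <- file.path(out_dir, "mdf.csv")
    readr::write_csv(tidyr::pivot_wider(
      tibble::as_tibble(mdf), names_from = "channel",
      values_from = "mdf_hz", names_glue = "{channel}_mdf_hz"), p,
      progress = FALSE)
    emit(p)

    log_line("detect", sprintf("drop fraction %g, min duration %g s",
                               dcfg$drop_fraction, dcfg$min_duration_s))
    ev <- detect_precursors(env, dcfg, track)
    thigh <- sum(attr(env, "channels")$muscle %in% c("quadriceps", "hamstring"))
    fused <- if (thigh >= 2 && min_channels >= 2) {
      fuse_events(ev, min_channels = min_channels)
    } else ev
    report <- NULL
    if (!is.null(track)) {
      fused <- match_events(fused, track)
      fused <- fold_change(fused, env, track)
      fused <- event_amplitude_scale(fused, filt)
      report <- evaluate_detection(fused, track)
    }
    p <- file.path(out_dir, "detection.json")
    jsonlite::write_json(
      c(stamp, list(events = as.data.frame(fused),
                    metrics = if (!is.null(report))
                      as.list(glance(report)) else NULL)),
      p, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null",
      null = "null")
    emit(p)

    comparison <- NULL
    if (!is.null(track) && nrow(fused) > 0) {
      log_line("stats", sprintf("precursor vs normal, %s unit", unit))
      iv <- precursor_intervals(fused, track,
                                guard_s = attr(env, "window_s"))
      comparison <- tryCatch(state_comparison(env, iv, unit = unit),
                             error = function(e) NULL)
    }
    p <- file.path(out_dir, "stats.json")
    jsonlite::write_json(
      c(stamp, if (is.null(comparison)) {
        list(note = "no precursor-vs-normal comparison (no detected events)")
      } else {
        list(comparison = as.list(glance(comparison)),
             group_means_mv = as.list(comparison$group_means))
      }),
      p, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null",
      null = "null")
    emit(p)

    log_line("done", sprintf("%d events, %d artifacts", nrow(fused),
                             length(written)))
    invisible(list(recording = rec, filtered = filt, envelope = env,
                   mdf = mdf, events = fused, report = report,
                   comparison = comparison,
                   paths = c(written, logf)))
  }

  tryCatch(run(), error = function(e) {
    unlink(written)
    abort(paste0("pipeline failed: ", conditionMessage(e)), parent = e)
  })
}
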