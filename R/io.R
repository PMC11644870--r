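#' Read an sEMG recording from its CSV dialect
#'
#' The dialect is plain UTF-8 CSV: line 1 is a metadata comment
#' `# fs_hz=<float> t0_s=<float>`, line 2 the header
#' `time_s,<label1>,<label2>,...`, then one row per sample with time in
#' seconds and amplitudes in millivolts. Channel labels embed the electrode
#' placement as `<side>_<muscle>[suffix]`.
#'
#' @param path Path to a recording CSV file.
#' @return An [new_recording()] object.
#' @seealso [write_recording()]
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  meta <- readLines(path, n = 1L)
  mm <- regmatches(meta, regexec(
    "^#\\s*fs_hz=([0-9eE.+-]+)\\s+t0_s=([0-9eE.+-]+)\\s*$", meta))[[1]]
  if (length(mm) != 3L) {
    abort("format error: missing '# fs_hz=... t0_s=...' metadata line")
  }
  fs <- as.numeric(mm[2]); t0 <- as.numeric(mm[3])
  if (!is.finite(fs) || fs <= 0) abort("format error: invalid fs_hz")
  # cells are parsed with base R's strtod so stored doubles come back bit
  # for bit; readr's fast parser can be off by one ulp
  df <- readr::read_csv(path, skip = 1L, show_col_types = FALSE,
                        progress = FALSE, col_types = readr::cols(
                          .default = readr::col_character()))
  if (names(df)[1] != "time_s") abort("format error: first column must be time_s")
  if (ncol(df) < 2L) abort("format error: no channel columns")
  if (nrow(df) < 1L) abort("format error: no data rows")
  for (j in seq_along(df)) {
    num <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(!is.finite(num))
    if (length(bad) > 0) {
      abort(sprintf("data error: missing/NaN/non-numeric cell at row %d, column %d (%s)",
                    bad[1], j, names(df)[j]))
    }
    df[[j]] <- num
  }
  if (nrow(df) > 1 && any(diff(df$time_s) <= 0)) {
    abort("format error: time_s must be strictly increasing")
  }
  labels <- names(df)[-1]
  mm <- regmatches(labels, regexec(
    paste0("^(", paste(.semg_sides, collapse = "|"), ")_(",
           paste(.semg_muscles, collapse = "|"), ")"), labels))
  ok <- vapply(mm, length, 0L) == 3L
  if (!all(ok)) {
    abort(paste0("format error: channel label '", labels[!ok][1],
                 "' does not start with '<side>_<muscle>'"))
  }
  ch <- channel_meta(muscle = vapply(mm, `[`, "", 3L),
                     side = vapply(mm, `[`, "", 2L), label = labels)
  rec <- new_recording(as.matrix(df[, -1, drop = FALSE]), fs, ch, t0)
  rec$time_s <- df$time_s   # keep stored times for exact round trips
  rec
}

#' Write an sEMG recording to its CSV dialect
#'
#' @param rec An `semg_recording`.
#' @param path Output file path.
#' @return `path`, invisibly. Reading the file back reproduces `rec` to full
#'   stored precision.
#' @export
write_recording <- function(rec, path) {
  if (!inherits(rec, "semg_recording")) abort("rec must be an semg_recording")
  if (length(channel_labels(rec)) < 1L) abort("zero-channel recording rejected")
  writeLines(sprintf("# fs_hz=%s t0_s=%s",
                     format(sample_rate(rec), digits = 17),
                     format(recording_t0(rec), digits = 17)), path)
  # doubles are serialized with 17 significant digits so a read-back
  # reproduces every value bit for bit
  df <- as.data.frame(lapply(as.data.frame(rec), function(x) {
    sprintf("%.17g", x)
  }))
  names(df) <- names(rec)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE,
                   eol = "\n", progress = FALSE, quote = "none")
  invisible(path)
}

#' Read / write annotation tracks
#'
#' Annotation CSV dialect: header `label,start_s,end_s,frame_index`; empty
#' cells mean "none". Events are sorted by `start_s` on read.
#'
#' @param path Path to an annotation CSV file.
#' @param video_fps Frame rate to attach to the track (not stored in the
#'   file; default 33 frames/s).
#' @return [read_annotations()] returns an `semg_annotations` track;
#'   [write_annotations()] returns `path` invisibly.
#' @export
read_annotations <- function(path, video_fps = 33) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          label = readr::col_character(),
                          start_s = readr::col_double(),
                          end_s = readr::col_double(),
                          frame_index = readr::col_integer()))
  if (!identical(names(df), c("label", "start_s", "end_s", "frame_index"))) {
    abort("format error: header must be label,start_s,end_s,frame_index")
  }
  annotations(df$label, df$start_s, df$end_s, df$frame_index,
              video_fps = video_fps)
}

#' @rdname read_annotations
#' @param track An `semg_annotations` track.
#' @export
write_annotations <- function(track, path) {
  if (!inherits(track, "semg_annotations")) {
    abort("track must be an semg_annotations object")
  }
  df <- as.data.frame(track)
  for (col in c("start_s", "end_s")) {
    df[[col]] <- ifelse(is.na(df[[col]]), NA_character_,
                        sprintf("%.17g", df[[col]]))
  }
  readr::write_csv(df, path, na = "", eol = "\n", progress = FALSE,
                   quote = "none")
  invisible(path)
}
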