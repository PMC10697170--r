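#' Read and write the pipeline's CSV formats
#'
#' Gaze samples use columns `time_ms`, `xL_deg`, `yL_deg`, `xR_deg`,
#' `yR_deg`, `pupL`, `pupR` (plus optional `trial_id`); trial events use
#' the [sample_trial_sequence()] schema. The same schemas are accepted for
#' exported real data.
#'
#' @param path File path.
#' @param x Tibble to write.
#' @return A tibble (readers) or `path`, invisibly (writers).
#' @name oseq_io
NULL

#' @rdname oseq_io
#' @export
read_gaze_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  assert_cols(out, c("time_ms", "xL_deg", "yL_deg", "xR_deg", "yR_deg",
                     "pupL", "pupR"), "gaze file")
  out
}

#' @rdname oseq_io
#' @export
write_gaze_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname oseq_io
#' @export
read_events_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  assert_cols(out, c("trial_id", "subject", "foreperiod_ms",
                     "cue_onset_ms", "target_onset_ms"), "events file")
  out
}

#' @rdname oseq_io
#' @export
write_events_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' Read a plain-text eye-tracker sample dump
#'
#' TAB-separated columns without header: time, xL, yL, pupL, xR, yR, pupR,
#' the layout of common binocular ASCII exports. Position units are passed
#' through; convert pixels with [pixels_to_degrees()] if needed.
#'
#' @param path File path.
#' @param na Strings treated as missing samples (e.g. `"."`).
#' @return A tibble in the standard gaze schema.
#' @export
read_tracker_ascii <- function(path, na = c(".", "NA", "")) {
  out <- readr::read_tsv(path,
                         col_names = c("time_ms", "xL_deg", "yL_deg", "pupL",
                                       "xR_deg", "yR_deg", "pupR"),
                         na = na, show_col_types = FALSE,
                         comment = "#")
  out[, c("time_ms", "xL_deg", "yL_deg", "xR_deg", "yR_deg", "pupL", "pupR")]
}
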