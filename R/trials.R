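#' Flag a pretarget-window saccade
#'
#' TRUE iff at least one saccade onset falls inside the pretarget decision
#' window, by default \[-300, 0) ms relative to target onset (half-open:
#' an onset at exactly 0 belongs to the post-target epoch). The measure is
#' presence/absence, not a count.
#'
#' @param onset_ms Saccade onsets (ms, target-relative) for one trial.
#' @param window Length-2 window \[lo, hi) in ms.
#' @return Logical scalar.
#' @examples
#' window_saccade_flag(c(-350, -150))  # TRUE
#' window_saccade_flag(-350)           # FALSE
#' @export
window_saccade_flag <- function(onset_ms, window = c(-300, 0)) {
  any(onset_ms >= window[1L] & onset_ms < window[2L], na.rm = TRUE)
}

#' Mark excluded trials
#'
#' A trial is excluded when it is the first trial of a session (no previous
#' foreperiod) or when a blink exclusion interval or missing-data span
#' intersects the pretarget window. Reasons are recorded with first-match
#' precedence: `first_trial` before `blink_or_missing_in_window`.
#'
#' @param trials Trial table with `trial_id` and `first_of_session`.
#' @param blinks Blink table from [detect_blinks()] (may be `NULL`/empty).
#' @param window Pretarget window \[lo, hi) in ms.
#' @return `trials` with logical `excluded` and `exclusion_reason`
#'   (`"first_trial"`, `"blink_or_missing_in_window"` or `"none"`).
#' @export
apply_exclusions <- function(trials, blinks = NULL, window = c(-300, 0)) {
  assert_cols(trials, c("trial_id", "first_of_session"))
  blink_hit <- rep(FALSE, nrow(trials))
  if (!is.null(blinks) && nrow(blinks)) {
    bad <- blinks %>%
      filter(.data$excl_onset_ms < window[2L],
             .data$excl_offset_ms >= window[1L]) %>%
      pull("trial_id") %>% unique()
    blink_hit <- trials$trial_id %in% bad
  }
  trials %>%
    mutate(
      excluded = .data$first_of_session | blink_hit,
      exclusion_reason = dplyr::case_when(
        .data$first_of_session ~ "first_trial",
        blink_hit ~ "blink_or_missing_in_window",
        TRUE ~ "none"
      )
    )
}

#' Compute the foreperiod difference and its z-scaled version (SFD)
#'
#' Adds `fp_difference_ms = foreperiod_ms - prev_foreperiod_ms` and the
#' standardized foreperiod difference `sfd`, z-scaled (sample SD, n-1) over
#' all included trials pooled across subjects and groups. Setting
#' `per_group = TRUE` scales within each foreperiod-distribution group
#' instead.
#'
#' @param trials Trial table with `prev_foreperiod_ms` populated for
#'   non-session-first trials and (ideally) an `excluded` column; trials
#'   marked excluded do not enter the scaling statistics.
#' @param per_group Scale within `distribution` groups instead of pooled.
#' @return `trials` with `fp_difference_ms` and `sfd` columns.
#' @export
compute_sfd <- function(trials, per_group = FALSE) {
  assert_cols(trials, c("foreperiod_ms", "prev_foreperiod_ms"))
  trials <- mutate(trials,
                   fp_difference_ms = .data$foreperiod_ms - .data$prev_foreperiod_ms)
  incl <- if ("excluded" %in% names(trials)) !trials$excluded else
    !is.na(trials$fp_difference_ms)
  incl <- incl & !is.na(trials$fp_difference_ms)
  scale_by <- if (per_group && "distribution" %in% names(trials))
    trials$distribution else rep("all", nrow(trials))
  trials$sfd <- NA_real_
  for (g in unique(scale_by[incl])) {
    sel <- incl & scale_by == g
    m <- mean(trials$fp_difference_ms[sel])
    s <- sd(trials$fp_difference_ms[sel])
    if (is.na(s) || s == 0) abort("Zero SD of foreperiod differences; cannot z-scale.")
    idx <- scale_by == g & !is.na(trials$fp_difference_ms)
    trials$sfd[idx] <- (trials$fp_difference_ms[idx] - m) / s
  }
  trials
}

#' Screen random-block trials for matching previous foreperiod
#'
#' Fixed/random designs: random-block trials are kept only when the
#' previous trial's foreperiod equals the current one (so the n-1 identity
#' matches the fixed blocks, where this holds by construction). Fixed-block
#' trials are all kept; session-first trials (no previous foreperiod) are
#' dropped. Idempotent.
#'
#' @param trials Trial table with `condition` and `prev_foreperiod_ms`.
#' @return Filtered tibble.
#' @export
screen_prev_equal <- function(trials) {
  assert_cols(trials, c("condition", "foreperiod_ms", "prev_foreperiod_ms"))
  filter(trials,
         !is.na(.data$prev_foreperiod_ms),
         .data$condition == "fixed" |
           .data$prev_foreperiod_ms == .data$foreperiod_ms)
}

#' Build the trial-level analysis table
#'
#' Combines the trial-event table with detected saccades and blinks into
#' one row per trial: previous foreperiod (the previous *presented* trial
#' within subject, regardless of that trial's own analyzability),
#' foreperiod difference and its z-scaled version (SFD), the
#' pretarget-window saccade flag, and exclusion status. `saccade_present`
#' is `NA` for excluded trials.
#'
#' @param events Trial-event table from [sample_trial_sequence()] or
#'   [read_events_csv()].
#' @param saccades Saccade table from [detect_saccades()].
#' @param blinks Optional blink table from [detect_blinks()].
#' @param window Pretarget window \[lo, hi) ms.
#' @param per_group Passed to [compute_sfd()].
#' @return A tibble, one row per trial.
#' @export
build_trial_table <- function(events, saccades, blinks = NULL,
                              window = c(-300, 0), per_group = FALSE) {
  assert_cols(events, c("trial_id", "subject", "session", "block", "trial",
                        "foreperiod_ms", "first_of_session"))
  flags <- saccades %>%
    group_by(.data$trial_id) %>%
    summarise(saccade_present = window_saccade_flag(.data$onset_ms,
                                                    window = .env$window),
              .groups = "drop")
  out <- events %>%
    group_by(.data$subject) %>%
    arrange(.data$session, .data$block, .data$trial, .by_group = TRUE) %>%
    mutate(prev_foreperiod_ms = if_else(.data$first_of_session, NA_real_,
                                        dplyr::lag(.data$foreperiod_ms))) %>%
    ungroup() %>%
    left_join(flags, by = "trial_id") %>%
    mutate(saccade_present = dplyr::coalesce(.data$saccade_present, FALSE)) %>%
    apply_exclusions(blinks, window) %>%
    compute_sfd(per_group = per_group) %>%
    mutate(saccade_present = if_else(.data$excluded, NA, .data$saccade_present))
  out
}
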