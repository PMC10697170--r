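#' Screen geometry for pixel-to-degree conversion
#'
#' Default geometry: a 24-in. 16:9 LCD (53.1 x 29.9 cm visible panel,
#' 1920 x 1080 px) viewed from 100 cm.
#'
#' @param screen_px Width/height in pixels.
#' @param screen_cm Physical width/height of the panel (cm).
#' @param distance_cm Viewing distance (cm).
#' @return A list with class `"oseq_geometry"`.
#' @export
screen_geometry <- function(screen_px = c(1920, 1080),
                            screen_cm = c(53.1, 29.9),
                            distance_cm = 100) {
  if (any(screen_px <= 0) || any(screen_cm <= 0) || distance_cm <= 0) {
    abort("Screen geometry must be strictly positive.")
  }
  structure(list(screen_px = screen_px, screen_cm = screen_cm,
                 distance_cm = distance_cm), class = "oseq_geometry")
}

#' Convert pixel gaze coordinates to visual degrees
#'
#' Maps pixel coordinates to degrees of visual angle relative to screen
#' center, using the exact arctangent per axis (not the small-angle
#' approximation). The screen center is at pixel `(w + 1) / 2` on each axis.
#'
#' @param x_px,y_px Pixel coordinates (numeric vectors).
#' @param geometry A [screen_geometry()].
#' @return A tibble with columns `x_deg`, `y_deg`.
#' @examples
#' pixels_to_degrees(960.5, 540.5)        # screen center -> (0, 0)
#' @export
pixels_to_degrees <- function(x_px, y_px, geometry = screen_geometry()) {
  if (!inherits(geometry, "oseq_geometry")) abort("`geometry` must be an oseq_geometry.")
  cm_per_px <- geometry$screen_cm / geometry$screen_px
  cx <- (geometry$screen_px[1L] + 1) / 2
  cy <- (geometry$screen_px[2L] + 1) / 2
  tibble(
    x_deg = atan((x_px - cx) * cm_per_px[1L] / geometry$distance_cm) * 180 / pi,
    y_deg = atan((y_px - cy) * cm_per_px[2L] / geometry$distance_cm) * 180 / pi
  )
}

# Zero-phase low-pass filter of one numeric channel, applied per contiguous
# non-NA run. Each run is odd-reflection padded before filtering so that
# the forward-backward pass has no start-up transient at run boundaries.
# Runs shorter than the filter warm-up are returned unfiltered.
lowpass_channel <- function(x, bf, min_len, pad = 200L) {
  runs <- true_runs(!is.na(x))
  short <- 0L
  if (!is.null(runs) && nrow(runs)) for (i in seq_len(nrow(runs))) {
    idx <- runs[i, 1L]:runs[i, 2L]
    n <- length(idx)
    if (n >= min_len) {
      p <- min(pad, n - 1L)
      y <- x[idx]
      ypad <- c(2 * y[1L] - y[(p + 1L):2L], y, 2 * y[n] - y[(n - 1L):(n - p)])
      yf <- signal::filtfilt(bf, ypad)
      x[idx] <- yf[(p + 1L):(p + n)]
    } else {
      short <- short + 1L
    }
  }
  attr(x, "short_runs") <- short
  x
}

#' Low-pass filter gaze position channels
#'
#' Applies a zero-phase (forward-backward) 4th-order Butterworth low-pass
#' filter to the x/y position channels of each trial segment. Pupil
#' channels are left unfiltered. Missing spans (blinks) break the signal
#' into contiguous runs that are filtered independently; runs shorter than
#' the filter warm-up are passed through unchanged with a message.
#'
#' @param samples Gaze samples: a tibble with `xL_deg`, `yL_deg`, `xR_deg`,
#'   `yR_deg` columns and optionally `trial_id` (filtering is per trial).
#' @param cutoff Cutoff frequency, Hz.
#' @param sampling_rate Sampling rate, Hz.
#' @return `samples` with filtered position channels.
#' @export
lowpass_filter <- function(samples, cutoff = 60, sampling_rate = 1000) {
  if (cutoff >= sampling_rate / 2) {
    abort("`cutoff` must be below the Nyquist frequency.")
  }
  assert_cols(samples, c("xL_deg", "yL_deg", "xR_deg", "yR_deg"))
  bf <- signal::butter(4, cutoff / (sampling_rate / 2), type = "low")
  min_len <- 30L
  chans <- c("xL_deg", "yL_deg", "xR_deg", "yR_deg")
  grp <- if ("trial_id" %in% names(samples)) samples$trial_id else
    rep(1L, nrow(samples))
  short <- 0L
  split_idx <- split(seq_len(nrow(samples)), grp)
  for (ch in chans) {
    res <- samples[[ch]]
    for (idx in split_idx) {
      y <- lowpass_channel(res[idx], bf, min_len)
      short <- short + attr(y, "short_runs")
      res[idx] <- as.numeric(y)
    }
    samples[[ch]] <- res
  }
  if (short > 0) {
    inform(sprintf("lowpass_filter: %d run(s) shorter than the filter warm-up left unfiltered.", short))
  }
  samples
}

#' Segment a gaze recording into trial epochs
#'
#' Cuts samples into per-trial segments running from 500 ms before cue
#' onset to 500 ms after target onset, and rebases time so that target
#' onset is 0 ms (pretarget times negative). Sample intervals are half-open
#' `[t, t + 1)` ms.
#'
#' @param samples Gaze sample tibble with absolute `time_ms`. Timelines are
#'   absolute within subject: when both tables carry a `subject` column the
#'   segmentation is done per subject.
#' @param events Trial-event table with `trial_id`, `cue_onset_ms`,
#'   `target_onset_ms`, `foreperiod_ms`.
#' @return A tibble of segmented samples with `trial_id` and target-relative
#'   `t_rel` (ms); one segment spans `foreperiod_ms + 1000` samples.
#' @export
segment_gaze <- function(samples, events) {
  assert_cols(samples, "time_ms")
  assert_cols(events, c("trial_id", "cue_onset_ms", "target_onset_ms"))
  if ("subject" %in% names(samples) && "subject" %in% names(events) &&
      dplyr::n_distinct(events$subject) > 1L) {
    subj <- unique(events$subject)
    out <- purrr::map(subj, function(s) {
      segment_gaze(samples[samples$subject == s, , drop = FALSE],
                   events[events$subject == s, , drop = FALSE])
    })
    return(bind_rows(out))
  }
  ev <- arrange(events, .data$cue_onset_ms)
  lo <- ev$cue_onset_ms - 500
  hi <- ev$target_onset_ms + 500
  idx <- findInterval(samples$time_ms, lo)
  ok <- idx >= 1L & idx <= nrow(ev)
  ok[ok] <- samples$time_ms[ok] < hi[idx[ok]]
  seg <- samples[ok, , drop = FALSE]
  j <- idx[ok]
  seg$trial_id <- ev$trial_id[j]
  seg$t_rel <- seg$time_ms - ev$target_onset_ms[j]
  as_tibble(seg)
}

#' Detect blinks in trial segments
#'
#' Two criteria, unioned per trial: (a) spans of missing gaze or sentinel
#' (non-positive) pupil samples in either eye; (b) spans where the pupil
#' deviates from the segment's mean pupil size by more than
#' `pupil_sd_threshold` segment standard deviations in *both* eyes for at
#' least `min_run` consecutive samples. Overlapping intervals are merged,
#' and each detected blink is padded by `pad_ms` on both sides into an
#' exclusion interval (clipped to segment bounds).
#'
#' With `pupil_change = "diff"` criterion (b) is applied to the
#' sample-to-sample pupil change instead of the level deviation.
#'
#' @param segments Segmented samples from [segment_gaze()].
#' @param pupil_sd_threshold SD multiple for the pupil criterion.
#' @param min_run Minimum consecutive samples for the pupil criterion.
#' @param pad_ms Padding (ms) applied around each blink.
#' @param pupil_change `"level"` (deviation from the segment mean) or
#'   `"diff"` (first difference).
#' @return A tibble with one row per blink: `trial_id`, `onset_ms`,
#'   `offset_ms`, `source`, `excl_onset_ms`, `excl_offset_ms`
#'   (target-relative ms).
#' @export
detect_blinks <- function(segments, pupil_sd_threshold = 2.5, min_run = 3L,
                          pad_ms = 200, pupil_change = c("level", "diff")) {
  pupil_change <- match.arg(pupil_change)
  assert_cols(segments, c("trial_id", "t_rel", "xL_deg", "xR_deg",
                          "pupL", "pupR"))
  out <- segments %>%
    group_by(.data$trial_id) %>%
    dplyr::group_map(~ blink_one_segment(.x, .y$trial_id, pupil_sd_threshold,
                                         min_run, pad_ms, pupil_change)) %>%
    bind_rows()
  if (!nrow(out)) {
    out <- tibble(trial_id = integer(), onset_ms = numeric(),
                  offset_ms = numeric(), source = character(),
                  excl_onset_ms = numeric(), excl_offset_ms = numeric())
  }
  out
}

blink_one_segment <- function(seg, trial_id, thr, min_run, pad_ms, mode) {
  t <- seg$t_rel
  iv <- NULL
  src <- character(0)

  missing <- is.na(seg$xL_deg) | is.na(seg$xR_deg) |
    is.na(seg$pupL) | is.na(seg$pupR) | seg$pupL <= 0 | seg$pupR <= 0
  runs <- true_runs(missing)
  if (!is.null(runs) && nrow(runs)) {
    iv <- cbind(t[runs[, 1L]], t[runs[, 2L]])
    src <- rep("missing_gaze", nrow(runs))
  }

  dev <- function(p) {
    if (mode == "level") abs(p - mean(p, na.rm = TRUE))
    else abs(c(0, diff(p)))
  }
  sdl <- sd(seg$pupL, na.rm = TRUE); sdr <- sd(seg$pupR, na.rm = TRUE)
  if (is.na(sdl) || is.na(sdr) || sdl == 0 || sdr == 0) {
    inform("detect_blinks: zero pupil variance; pupil criterion skipped.")
  } else {
    hit <- dev(seg$pupL) > thr * sdl & dev(seg$pupR) > thr * sdr
    runs <- true_runs(hit)
    if (!is.null(runs) && nrow(runs)) {
      runs <- runs[runs[, 2L] - runs[, 1L] + 1L >= min_run, , drop = FALSE]
      if (nrow(runs)) {
        iv <- rbind(iv, cbind(t[runs[, 1L]], t[runs[, 2L]]))
        src <- c(src, rep("pupil_criterion", nrow(runs)))
      }
    }
  }
  if (is.null(iv) || !nrow(iv)) return(NULL)

  ord <- order(iv[, 1L])
  iv <- iv[ord, , drop = FALSE]; src <- src[ord]
  # merge overlapping intervals, keeping the first source label
  keep_iv <- iv[1L, , drop = FALSE]; keep_src <- src[1L]
  if (nrow(iv) > 1L) for (i in 2L:nrow(iv)) {
    j <- nrow(keep_iv)
    if (iv[i, 1L] <= keep_iv[j, 2L] + 1) {
      keep_iv[j, 2L] <- max(keep_iv[j, 2L], iv[i, 2L])
    } else {
      keep_iv <- rbind(keep_iv, iv[i, , drop = FALSE])
      keep_src <- c(keep_src, src[i])
    }
  }
  tibble(
    trial_id = trial_id,
    onset_ms = keep_iv[, 1L], offset_ms = keep_iv[, 2L],
    source = keep_src,
    excl_onset_ms = pmax(keep_iv[, 1L] - pad_ms, t[1L]),
    excl_offset_ms = pmin(keep_iv[, 2L] + pad_ms, t[length(t)])
  )
}
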