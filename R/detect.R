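#' Saccade-detection parameters
#'
#' Velocity-threshold detection settings: the threshold is `lambda`
#' median-based standard deviations above the segment's median velocity,
#' candidates must last at least `min_duration_samples` consecutive
#' samples, and a `min_intersaccadic_ms` interval between a saccade offset
#' and the next onset suppresses overshoot detections. `criterion` selects
#' between the elliptical per-axis threshold and a scalar-speed variant.
#'
#' @param lambda SD multiple for the velocity threshold.
#' @param min_duration_samples Minimum event duration, samples.
#' @param min_intersaccadic_ms Minimum offset-to-onset interval, ms.
#' @param velocity_window Width of the moving-window velocity estimator
#'   (samples; the 5-point stencil is the only supported width).
#' @param criterion `"elliptical"` or `"scalar"`.
#' @param max_amplitude Optional amplitude cap (deg); events larger than
#'   this are dropped (small-saccade-only analysis). `NULL` keeps all sizes.
#' @return A list with class `"oseq_detection_params"`.
#' @export
detection_params <- function(lambda = 6, min_duration_samples = 6L,
                             min_intersaccadic_ms = 50,
                             velocity_window = 5L,
                             criterion = c("elliptical", "scalar"),
                             max_amplitude = NULL) {
  criterion <- match.arg(criterion)
  if (any(c(lambda, min_duration_samples, min_intersaccadic_ms,
            velocity_window) <= 0)) {
    abort("Detection parameters must be strictly positive.")
  }
  if (velocity_window != 5L) abort("Only the 5-sample velocity window is supported.")
  structure(list(lambda = lambda,
                 min_duration_samples = as.integer(min_duration_samples),
                 min_intersaccadic_ms = min_intersaccadic_ms,
                 velocity_window = 5L, criterion = criterion,
                 max_amplitude = max_amplitude),
            class = "oseq_detection_params")
}

#' Two-dimensional eye velocity via the 5-point moving window
#'
#' `v(t) = (p(t+2) + p(t+1) - p(t-1) - p(t-2)) / (6 dt)` per axis, the
#' smoothing differentiator standard in velocity-threshold microsaccade
#' detection. The two samples at each end, and any sample whose window
#' touches missing data, are `NA`.
#'
#' @param x,y Position series (deg), sampled uniformly.
#' @param sampling_rate Sampling rate, Hz.
#' @return A tibble with columns `vx`, `vy` (deg/s).
#' @export
compute_velocity <- function(x, y, sampling_rate = 1000) {
  n <- length(x)
  if (n < 5L) return(tibble(vx = rep(NA_real_, n), vy = rep(NA_real_, n)))
  dt <- 1 / sampling_rate
  stencil <- function(p) {
    v <- rep(NA_real_, n)
    i <- 3L:(n - 2L)
    v[i] <- (p[i + 2L] + p[i + 1L] - p[i - 1L] - p[i - 2L]) / (6 * dt)
    v
  }
  tibble(vx = stencil(x), vy = stencil(y))
}

# Median-based robust SD: sigma^2 = median(v^2) - median(v)^2.
robust_sd <- function(v) {
  v <- v[!is.na(v)]
  sqrt(max(median(v^2) - median(v)^2, 0))
}

#' Flag samples exceeding the velocity threshold
#'
#' Flags samples whose velocity exceeds the segment's median velocity by
#' `lambda` or more median-based standard deviations. The elliptical
#' criterion tests `((vx - med_x)/(lambda sd_x))^2 +
#' ((vy - med_y)/(lambda sd_y))^2 > 1`; the scalar variant applies the same
#' rule to the speed `sqrt(vx^2 + vy^2)`.
#'
#' @param vx,vy Velocity series (deg/s); `NA` samples are never flagged.
#' @param lambda SD multiple.
#' @param criterion `"elliptical"` or `"scalar"`.
#' @return Logical vector.
#' @export
velocity_threshold <- function(vx, vy, lambda = 6,
                               criterion = c("elliptical", "scalar")) {
  criterion <- match.arg(criterion)
  if (sum(!is.na(vx)) < 10L) {
    abort("Too few unmasked velocity samples.", class = "oseq_degenerate_segment")
  }
  if (criterion == "elliptical") {
    sx <- robust_sd(vx); sy <- robust_sd(vy)
    if (sx <= 0 || sy <= 0) {
      abort("Degenerate segment: zero robust velocity SD.",
            class = "oseq_degenerate_segment")
    }
    mx <- median(vx, na.rm = TRUE); my <- median(vy, na.rm = TRUE)
    crit <- ((vx - mx) / (lambda * sx))^2 + ((vy - my) / (lambda * sy))^2
  } else {
    sp <- sqrt(vx^2 + vy^2)
    ss <- robust_sd(sp)
    if (is.na(ss) || ss <= 0) {
      abort("Degenerate segment: zero robust velocity SD.",
            class = "oseq_degenerate_segment")
    }
    crit <- ((sp - median(sp, na.rm = TRUE)) / (lambda * ss))^2
  }
  out <- !is.na(crit) & crit > 1
  out
}

#' Extract monocular saccade candidates from threshold flags
#'
#' Maximal runs of flagged samples lasting at least
#' `min_duration_samples` become candidates. A candidate whose onset
#' follows the previous accepted candidate's offset by less than
#' `min_intersaccadic_ms` is discarded as an overshoot, and candidates
#' intersecting any exclusion interval (blinks) are discarded.
#'
#' @param flags Logical vector from [velocity_threshold()].
#' @param t_rel Sample times (ms) aligned with `flags`.
#' @param params [detection_params()].
#' @param exclude Optional matrix-like of exclusion intervals with columns
#'   start/end (ms).
#' @return Tibble of candidates with `i_on`, `i_off` (sample indices) and
#'   `onset_ms`, `offset_ms`.
#' @export
extract_monocular_saccades <- function(flags, t_rel, params = detection_params(),
                                       exclude = NULL) {
  runs <- true_runs(flags)
  if (is.null(runs) || !nrow(runs)) {
    return(tibble(i_on = integer(), i_off = integer(),
                  onset_ms = numeric(), offset_ms = numeric()))
  }
  runs <- runs[runs[, 2L] - runs[, 1L] + 1L >= params$min_duration_samples, ,
               drop = FALSE]
  keep <- logical(nrow(runs))
  last_off <- -Inf
  for (i in seq_len(nrow(runs))) {
    onset <- t_rel[runs[i, 1L]]; offset <- t_rel[runs[i, 2L]]
    if (onset - last_off < params$min_intersaccadic_ms) next
    if (!is.null(exclude) && nrow(exclude) &&
        any(onset <= exclude[, 2L] & offset >= exclude[, 1L])) next
    keep[i] <- TRUE
    last_off <- offset
  }
  runs <- runs[keep, , drop = FALSE]
  tibble(i_on = runs[, 1L], i_off = runs[, 2L],
         onset_ms = t_rel[runs[, 1L]], offset_ms = t_rel[runs[, 2L]])
}

#' Merge monocular candidates into binocular saccades
#'
#' Only binocular saccades are retained: a left and a right candidate that
#' overlap by at least one sample are paired (greedy one-to-one pairing by
#' overlap length, ties broken by earlier onset). The merged event spans
#' the earlier onset to the later offset; amplitude and peak velocity are
#' averaged over the eyes.
#'
#' @param left,right Candidate tibbles with `onset_ms`, `offset_ms` and
#'   kinematics columns `amplitude`, `peak_velocity`.
#' @return Tibble of merged events.
#' @export
binocular_merge <- function(left, right) {
  empty <- tibble(onset_ms = numeric(), offset_ms = numeric(),
                  amplitude = numeric(), peak_velocity = numeric(),
                  onset_L = numeric(), offset_L = numeric(),
                  onset_R = numeric(), offset_R = numeric())
  if (!nrow(left) || !nrow(right)) return(empty)
  pairs <- NULL
  for (i in seq_len(nrow(left))) {
    for (j in seq_len(nrow(right))) {
      ov <- min(left$offset_ms[i], right$offset_ms[j]) -
        max(left$onset_ms[i], right$onset_ms[j])
      if (ov >= 0) pairs <- rbind(pairs, c(i, j, ov))
    }
  }
  if (is.null(pairs)) return(empty)
  ord <- order(-pairs[, 3L], pmin(left$onset_ms[pairs[, 1L]],
                                  right$onset_ms[pairs[, 2L]]))
  pairs <- pairs[ord, , drop = FALSE]
  used_l <- logical(nrow(left)); used_r <- logical(nrow(right))
  out <- list()
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    if (used_l[i] || used_r[j]) next
    used_l[i] <- TRUE; used_r[j] <- TRUE
    out[[length(out) + 1L]] <- tibble(
      onset_ms = min(left$onset_ms[i], right$onset_ms[j]),
      offset_ms = max(left$offset_ms[i], right$offset_ms[j]),
      amplitude = mean(c(left$amplitude[i], right$amplitude[j])),
      peak_velocity = mean(c(left$peak_velocity[i], right$peak_velocity[j])),
      onset_L = left$onset_ms[i], offset_L = left$offset_ms[i],
      onset_R = right$onset_ms[j], offset_R = right$offset_ms[j]
    )
  }
  arrange(bind_rows(out), .data$onset_ms)
}

# Attach displacement amplitude and peak speed to monocular candidates.
candidate_kinematics <- function(cand, x, y, vx, vy) {
  if (!nrow(cand)) {
    cand$amplitude <- numeric(0); cand$peak_velocity <- numeric(0)
    return(cand)
  }
  cand$amplitude <- sqrt((x[cand$i_off] - x[cand$i_on])^2 +
                         (y[cand$i_off] - y[cand$i_on])^2)
  cand$peak_velocity <- purrr::map2_dbl(cand$i_on, cand$i_off, function(a, b) {
    max(sqrt(vx[a:b]^2 + vy[a:b]^2), na.rm = TRUE)
  })
  cand
}

#' Detect binocular saccades in segmented gaze data
#'
#' Full detection pipeline per trial segment: 5-point velocity estimation
#' per eye, median-based velocity thresholding, extraction of monocular
#' candidates with the minimum-duration and intersaccadic-interval rules,
#' exclusion of candidates intersecting blink exclusion intervals, and
#' binocular merging. Degenerate segments (zero robust velocity SD) yield
#' no events and are counted in the `"degenerate_trials"` attribute.
#'
#' @param segments Segmented (ideally low-pass filtered) samples from
#'   [segment_gaze()].
#' @param blinks Optional blink table from [detect_blinks()]; candidates
#'   overlapping `excl_onset_ms`/`excl_offset_ms` are discarded.
#' @param params [detection_params()].
#' @return A saccade tibble: `trial_id`, `onset_ms`, `offset_ms` (ms,
#'   target-relative), `amplitude` (deg), `peak_velocity` (deg/s), per-eye
#'   onsets/offsets.
#' @export
detect_saccades <- function(segments, blinks = NULL,
                            params = detection_params()) {
  assert_cols(segments, c("trial_id", "t_rel", "xL_deg", "yL_deg",
                          "xR_deg", "yR_deg"))
  degenerate <- 0L
  res <- segments %>%
    group_by(.data$trial_id) %>%
    dplyr::group_map(function(seg, key) {
      excl <- NULL
      if (!is.null(blinks) && nrow(blinks)) {
        b <- blinks[blinks$trial_id == key$trial_id, , drop = FALSE]
        if (nrow(b)) excl <- cbind(b$excl_onset_ms, b$excl_offset_ms)
      }
      ev <- tryCatch(
        detect_one_segment(seg, params, excl),
        oseq_degenerate_segment = function(e) {
          degenerate <<- degenerate + 1L
          NULL
        })
      if (is.null(ev) || !nrow(ev)) return(NULL)
      ev$trial_id <- key$trial_id
      ev
    }) %>%
    bind_rows()
  if (!nrow(res)) {
    res <- tibble(onset_ms = numeric(), offset_ms = numeric(),
                  amplitude = numeric(), peak_velocity = numeric(),
                  onset_L = numeric(), offset_L = numeric(),
                  onset_R = numeric(), offset_R = numeric(),
                  trial_id = integer())
  }
  if (!is.null(params$max_amplitude)) {
    res <- filter(res, .data$amplitude <= params$max_amplitude)
  }
  res <- select(res, "trial_id", dplyr::everything())
  attr(res, "degenerate_trials") <- degenerate
  res
}

detect_one_segment <- function(seg, params, excl) {
  vl <- compute_velocity(seg$xL_deg, seg$yL_deg)
  vr <- compute_velocity(seg$xR_deg, seg$yR_deg)
  fl <- velocity_threshold(vl$vx, vl$vy, params$lambda, params$criterion)
  fr <- velocity_threshold(vr$vx, vr$vy, params$lambda, params$criterion)
  cl <- extract_monocular_saccades(fl, seg$t_rel, params, excl)
  cr <- extract_monocular_saccades(fr, seg$t_rel, params, excl)
  cl <- candidate_kinematics(cl, seg$xL_deg, seg$yL_deg, vl$vx, vl$vy)
  cr <- candidate_kinematics(cr, seg$xR_deg, seg$yR_deg, vr$vx, vr$vy)
  ev <- binocular_merge(cl, cr)
  # merged onsets/offsets can re-violate the intersaccadic rule; re-apply
  if (nrow(ev) > 1L) {
    keep <- logical(nrow(ev)); last_off <- -Inf
    for (i in seq_len(nrow(ev))) {
      if (ev$onset_ms[i] - last_off >= params$min_intersaccadic_ms) {
        keep[i] <- TRUE; last_off <- ev$offset_ms[i]
      }
    }
    ev <- ev[keep, , drop = FALSE]
  }
  ev
}

#' Main-sequence quality control
#'
#' Per participant, the Pearson correlation between log saccade amplitude
#' and log peak velocity (the main sequence). Detection is considered
#' valid when `r > 0.9`. Participants with fewer than `min_events` events
#' are flagged indeterminate (`pass = NA`), not failed.
#'
#' @param saccades Saccade table from [detect_saccades()].
#' @param trials Trial table mapping `trial_id` to `subject`.
#' @param min_events Minimum number of events for a determinate check.
#' @return A tibble with `subject`, `n_events`, `r`, `pass`.
#' @export
main_sequence_check <- function(saccades, trials, min_events = 10L) {
  assert_cols(saccades, c("trial_id", "amplitude", "peak_velocity"))
  assert_cols(trials, c("trial_id", "subject"))
  saccades %>%
    left_join(select(trials, "trial_id", "subject"), by = "trial_id") %>%
    filter(.data$amplitude > 0, .data$peak_velocity > 0) %>%
    group_by(.data$subject) %>%
    summarise(
      n_events = dplyr::n(),
      r = if (dplyr::n() >= 3L)
        stats::cor(log(.data$amplitude), log(.data$peak_velocity))
      else NA_real_,
      .groups = "drop"
    ) %>%
    mutate(pass = if_else(.data$n_events >= min_events, .data$r > 0.9, NA))
}
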