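#' Planted logistic model of pretarget saccade probability
#'
#' Describes the generative model used to plant ground-truth saccade
#' presence in the pretarget decision window. On the log-odds scale, for
#' trial with standardized foreperiod difference `s` and sum-coded
#' distribution covariate `x` (+1 uniform, -1 inverse-U):
#' \deqn{logit(p) = \beta_0 + b_{0j} + (\beta_{lin} + b_{1j}) s +
#'   \beta_{quad} s^2 + \beta_{dist} x + \beta_{dl} x s + \beta_{dq} x s^2}
#' with subject random effects \eqn{b_{0j} \sim N(0, \sigma_0^2)},
#' \eqn{b_{1j} \sim N(0, \sigma_1^2)}.
#'
#' Default slopes use the magnitudes reported for the oculomotor sequential
#' effect (linear -0.238, quadratic 0.081) so that recovery of planted
#' coefficients can be tested at study scale. The default between-subject
#' slope SD (0.23) is chosen so that, at 40 subjects, the simulated
#' standard error of the linear coefficient matches the precision implied
#' by the reported Wald statistic (z about -6 for -0.238, i.e. SE about
#' 0.039); the slope SD dominates that SE at study scale.
#'
#' @param beta0 Intercept (log-odds of a window saccade at `s = 0`).
#' @param beta_lin,beta_quad Linear and quadratic coefficients on the
#'   standardized foreperiod difference.
#' @param beta_dist Distribution main effect (sum-coded, +1 = uniform).
#' @param beta_dist_lin,beta_dist_quad Distribution-by-SFD interactions.
#' @param subject_sd_intercept,subject_sd_slope Standard deviations of the
#'   by-subject random intercept and random SFD slope; must be >= 0.
#' @return A list with class `"oseq_planted_model"`.
#' @export
planted_model <- function(beta0 = -1.4,
                          beta_lin = -0.238,
                          beta_quad = 0.081,
                          beta_dist = -0.2,
                          beta_dist_lin = 0.038,
                          beta_dist_quad = 0.022,
                          subject_sd_intercept = 0.5,
                          subject_sd_slope = 0.23) {
  sds <- c(subject_sd_intercept, subject_sd_slope)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    abort("Random-effect standard deviations must be finite and >= 0.")
  }
  structure(list(
    beta0 = beta0, beta_lin = beta_lin, beta_quad = beta_quad,
    beta_dist = beta_dist, beta_dist_lin = beta_dist_lin,
    beta_dist_quad = beta_dist_quad,
    subject_sd_intercept = subject_sd_intercept,
    subject_sd_slope = subject_sd_slope
  ), class = "oseq_planted_model")
}

#' Saccade/blink kinematics for gaze synthesis
#'
#' Parameters controlling the synthetic binocular gaze signal. Saccades
#' follow the main sequence: planted peak velocity equals
#' `main_sequence_slope * amplitude^main_sequence_exponent` (deg/s), and the
#' raised-cosine displacement profile then fixes the duration at
#' `1000 * pi * amplitude / (2 * peak_velocity)` ms. Amplitudes are
#' log-normal and predominantly below 1 degree, matching fixational
#' (micro)saccade statistics; `max_amplitude` caps displacements so that
#' gaze never leaves the 1.5-degree fixation-control radius.
#'
#' @param main_sequence_slope Main-sequence gain, (deg/s) per deg^exponent.
#' @param main_sequence_exponent Main-sequence exponent (1 = linear law).
#' @param amplitude_meanlog,amplitude_sdlog Log-normal amplitude parameters
#'   (deg). Defaults put ~91% of amplitudes below 1 degree.
#' @param max_amplitude Hard cap on planted amplitude (deg); must keep the
#'   eye inside the 1.5-degree fixation bound.
#' @param drift_sd Ocular drift innovation SD, deg per sqrt(sample).
#' @param drift_reversion Mean-reversion rate of the drift process toward
#'   screen center (per sample); keeps fixation bounded.
#' @param noise_sd Per-eye white measurement noise SD (deg).
#' @param background_rate Saccade rate (events/s) outside the pretarget
#'   decision window; within-window saccades are governed by the planted
#'   logistic model instead.
#' @param blink_rate Blink rate, events/min.
#' @param blink_duration_ms Length-2 range of blink core durations (ms).
#' @param pupil_baseline Baseline pupil size (arbitrary units).
#' @param pupil_noise_sd SD of slow pupil fluctuations (a.u.).
#' @return A list with class `"oseq_kinematics"`.
#' @export
kinematics_spec <- function(main_sequence_slope = 60,
                            main_sequence_exponent = 1,
                            amplitude_meanlog = -0.94,
                            amplitude_sdlog = 0.7,
                            max_amplitude = 1.2,
                            drift_sd = 0.002,
                            drift_reversion = 0.002,
                            noise_sd = 0.01,
                            background_rate = 1.2,
                            blink_rate = 3,
                            blink_duration_ms = c(100, 300),
                            pupil_baseline = 1000,
                            pupil_noise_sd = 4) {
  if (main_sequence_slope <= 0) abort("`main_sequence_slope` must be > 0.")
  if (max_amplitude >= 1.5) {
    abort("`max_amplitude` must stay below the 1.5-degree fixation bound.")
  }
  if (length(blink_duration_ms) != 2L || any(blink_duration_ms <= 0) ||
      diff(blink_duration_ms) < 0) {
    abort("`blink_duration_ms` must be an increasing positive range.")
  }
  structure(as.list(environment()), class = "oseq_kinematics")
}

# Sum-coded distribution covariate: +1 uniform, -1 inverse-U, 0 when absent.
dist_code <- function(distribution) {
  dplyr::case_when(distribution == "uniform" ~ 1,
                   distribution == "inverse_u" ~ -1,
                   TRUE ~ 0)
}

#' Plant ground-truth window-saccade flags from a logistic model
#'
#' Adds to the trial table a Bernoulli ground-truth flag `saccade_window`
#' drawn from the planted logistic model evaluated at each trial's
#' standardized foreperiod difference (SFD). The SFD is computed from the
#' trial sequence exactly as the analysis pipeline does: the foreperiod
#' difference `FP_n - FP_{n-1}` (previous presented trial within subject),
#' z-scaled over all non-session-first trials pooled across subjects.
#' Session-first trials have no SFD; they are planted at `sfd = 0` and are
#' excluded from analysis downstream.
#'
#' @param trials A trial table from [sample_trial_sequence()].
#' @param model A [planted_model()].
#' @param seed Integer seed for the Bernoulli draws and random effects.
#' @return `trials` with added columns `fp_difference_ms`, `sfd_true`, and
#'   logical `saccade_window`; subject random effects are attached as the
#'   `"ranef"` attribute.
#' @export
plant_window_saccades <- function(trials, model, seed = NULL) {
  if (!inherits(model, "oseq_planted_model")) {
    abort("`model` must be an oseq_planted_model.")
  }
  assert_cols(trials, c("subject", "foreperiod_ms", "first_of_session"))
  with_rng(seed, {
    trials <- trials %>%
      group_by(.data$subject) %>%
      arrange(.data$session, .data$block, .data$trial, .by_group = TRUE) %>%
      mutate(prev_fp = dplyr::lag(.data$foreperiod_ms)) %>%
      ungroup() %>%
      mutate(
        fp_difference_ms = if_else(.data$first_of_session, NA_real_,
                                   .data$foreperiod_ms - .data$prev_fp)
      )
    d <- trials$fp_difference_ms
    usable <- !is.na(d)
    if (sum(usable) >= 2L && sd(d[usable]) > 0) {
      sfd <- (d - mean(d[usable])) / sd(d[usable])
    } else {
      sfd <- d * 0
    }
    sfd[!usable] <- 0
    subj <- unique(trials$subject)
    re <- tibble(
      subject = subj,
      b0 = rnorm(length(subj), 0, model$subject_sd_intercept),
      b1 = rnorm(length(subj), 0, model$subject_sd_slope)
    )
    idx <- match(trials$subject, re$subject)
    x <- dist_code(trials$distribution)
    eta <- model$beta0 + re$b0[idx] +
      (model$beta_lin + re$b1[idx]) * sfd +
      model$beta_quad * sfd^2 +
      model$beta_dist * x +
      model$beta_dist_lin * x * sfd +
      model$beta_dist_quad * x * sfd^2
    if (any(!is.finite(eta))) abort("Planted model produced non-finite logits.")
    out <- trials %>%
      mutate(sfd_true = sfd,
             saccade_window = rbinom(dplyr::n(), 1L, plogis(eta)) == 1L) %>%
      select(-"prev_fp")
    attr(out, "ranef") <- re
    out
  })
}

#' Plant window saccades for a fixed/random foreperiod design
#'
#' Generative counterpart of the condition-by-foreperiod analysis: the
#' log-odds of a pretarget saccade are
#' `beta0 + b0 + beta_condition * c + (beta_foreperiod + b1) * f +
#'  beta_interaction * c * f`, where `c` is sum-coded condition (+1 fixed,
#' -1 random) and `f` the foreperiod in seconds, centered on the design mean.
#'
#' @param trials Trial table from an `"exp2"` [sample_trial_sequence()].
#' @param beta0,beta_condition,beta_foreperiod,beta_interaction Fixed
#'   effects on the log-odds scale.
#' @param subject_sd_intercept,subject_sd_slope Random-effect SDs.
#' @param seed Integer seed.
#' @return `trials` with added `saccade_window` (logical ground truth).
#' @export
plant_condition_saccades <- function(trials, beta0 = -1.4,
                                     beta_condition = -0.15,
                                     beta_foreperiod = 0,
                                     beta_interaction = 0,
                                     subject_sd_intercept = 0.5,
                                     subject_sd_slope = 0.1,
                                     seed = NULL) {
  assert_cols(trials, c("subject", "condition", "foreperiod_ms"))
  with_rng(seed, {
    subj <- unique(trials$subject)
    b0 <- rnorm(length(subj), 0, subject_sd_intercept)
    b1 <- rnorm(length(subj), 0, subject_sd_slope)
    idx <- match(trials$subject, subj)
    cc <- if_else(trials$condition == "fixed", 1, -1)
    f <- (trials$foreperiod_ms - mean(unique(trials$foreperiod_ms))) / 1000
    eta <- beta0 + b0[idx] + beta_condition * cc +
      (beta_foreperiod + b1[idx]) * f + beta_interaction * cc * f
    trials %>% mutate(saccade_window = rbinom(dplyr::n(), 1L, plogis(eta)) == 1L)
  })
}

# Duration (ms) of a raised-cosine saccade honoring the main-sequence law.
saccade_duration_ms <- function(amplitude, kin) {
  v_peak <- kin$main_sequence_slope * amplitude^kin$main_sequence_exponent
  pmax(6, round(1000 * pi * amplitude / (2 * v_peak)))
}

# Raised-cosine displacement profile sampled at 1 kHz: s(t) = A(1-cos(pi
# t/D))/2, evaluated at samples 1..d_ms (cumulative displacement).
raised_cosine_profile <- function(amplitude, d_ms) {
  tt <- seq_len(d_ms)
  amplitude * (1 - cos(pi * tt / d_ms)) / 2
}

#' Synthesize binocular gaze recordings with planted events
#'
#' Produces 1000-Hz binocular x/y/pupil traces for every trial segment
#' (from 500 ms before cue onset to 500 ms after target onset), containing
#' mean-reverting ocular drift, white measurement noise, planted saccades
#' with raised-cosine profiles obeying the main-sequence law, and blinks
#' (pupil dropout to 0 with gaze missing). Trials flagged `saccade_window`
#' receive exactly one planted saccade with onset uniform in \[-300, 0) ms
#' relative to target onset; background saccades are planted outside that
#' window at `kin$background_rate`. Saccade direction biases toward screen
#' center so that, mirroring the online fixation control, no planted event
#' takes gaze 1.5 degrees or more from center.
#'
#' @param trials Trial table, typically from [plant_window_saccades()]. A
#'   missing `saccade_window` column means no window saccades are planted.
#' @param kin A [kinematics_spec()].
#' @param seed Integer seed.
#' @return A list of class `"oseq_gaze"` with elements `samples` (tibble:
#'   `subject`, `trial_id`, `time_ms` (absolute within subject), `xL_deg`,
#'   `yL_deg`, `xR_deg`, `yR_deg`,
#'   `pupL`, `pupR`), `truth` (tibble of planted events with onset/offset in
#'   target-relative ms, amplitude, peak velocity, `in_window`), and
#'   `sampling_rate`.
#' @export
synthesize_gaze <- function(trials, kin = kinematics_spec(), seed = NULL) {
  if (!inherits(kin, "oseq_kinematics")) abort("`kin` must be an oseq_kinematics.")
  assert_cols(trials, c("trial_id", "subject", "foreperiod_ms",
                        "cue_onset_ms", "target_onset_ms"))
  if (!"saccade_window" %in% names(trials)) trials$saccade_window <- FALSE
  with_rng(seed, {
    per_trial <- purrr::map(seq_len(nrow(trials)), function(i) {
      synth_trial(trials[i, ], kin)
    })
    samples <- bind_rows(purrr::map(per_trial, "samples"))
    truth <- bind_rows(purrr::map(per_trial, "truth"))
    structure(list(samples = samples, truth = truth, sampling_rate = 1000),
              class = "oseq_gaze")
  })
}

#' @export
print.oseq_gaze <- function(x, ...) {
  cat("<oseq_gaze> ", nrow(x$samples), " samples @ ", x$sampling_rate,
      " Hz, ", nrow(x$truth), " planted events\n", sep = "")
  invisible(x)
}

# One trial's binocular traces plus ground-truth events. Time origin for
# event bookkeeping is target onset (pretarget times negative).
synth_trial <- function(tr, kin) {
  fp <- tr$foreperiod_ms
  t_rel <- seq(-(fp + 500), 500 - 1)          # segment, target-relative ms
  n <- length(t_rel)

  # --- plant events ---------------------------------------------------
  ev <- list()
  if (isTRUE(tr$saccade_window)) {
    ev[[1L]] <- runif(1, -300, 0)
  }
  # background saccades outside [-300, 0): pre-window and post-target spans
  spans <- rbind(c(t_rel[1L] + 30, -360), c(20, 470))
  spans <- spans[spans[, 2L] > spans[, 1L], , drop = FALSE]
  if (nrow(spans) && kin$background_rate > 0) {
    lens <- spans[, 2L] - spans[, 1L]
    k <- rpois(1L, kin$background_rate * sum(lens) / 1000)
    if (k > 0) {
      u <- runif(k, 0, sum(lens))
      onset <- numeric(k)
      for (j in seq_len(k)) {
        s <- findInterval(u[j], cumsum(c(0, lens)), rightmost.closed = TRUE)
        onset[j] <- spans[s, 1L] + (u[j] - cumsum(c(0, lens))[s])
      }
      ev <- c(ev, as.list(onset))
    }
  }
  cand <- unlist(ev)
  # greedy separation: the window saccade (first candidate, if any) has
  # priority, then earlier background onsets; keep onsets >= 120 ms apart
  onsets <- numeric(0)
  for (o in cand) {
    if (!length(onsets) || all(abs(o - onsets) >= 120)) onsets <- c(onsets, o)
  }
  onsets <- sort(onsets)

  # --- drift path (shared by both eyes) --------------------------------
  innov_x <- rnorm(n, 0, kin$drift_sd)
  innov_y <- rnorm(n, 0, kin$drift_sd)
  a <- 1 - kin$drift_reversion
  drift_x <- stats::filter(innov_x, a, method = "recursive")
  drift_y <- stats::filter(innov_y, a, method = "recursive")
  px <- as.numeric(drift_x); py <- as.numeric(drift_y)

  # --- add saccades ----------------------------------------------------
  truth <- NULL
  if (length(onsets)) {
    amp <- pmin(rlnorm(length(onsets), kin$amplitude_meanlog,
                       kin$amplitude_sdlog), kin$max_amplitude)
    d_ms <- saccade_duration_ms(amp, kin)
    v_peak <- kin$main_sequence_slope * amp^kin$main_sequence_exponent
    add_x <- numeric(n); add_y <- numeric(n)
    cum_x <- 0; cum_y <- 0
    rows <- vector("list", length(onsets))
    for (j in seq_along(onsets)) {
      i0 <- which.min(abs(t_rel - onsets[j]))
      pos0 <- c(px[i0] + cum_x, py[i0] + cum_y)
      # direct toward center when eccentric, otherwise random direction
      theta <- if (sqrt(sum(pos0^2)) > 0.25) {
        atan2(-pos0[2L], -pos0[1L]) + rnorm(1, 0, 0.3)
      } else runif(1, 0, 2 * pi)
      # keep the landing point inside the fixation bound
      a_j <- amp[j]
      land <- pos0 + a_j * c(cos(theta), sin(theta))
      if (sqrt(sum(land^2)) > 1.4) {
        theta <- atan2(-pos0[2L], -pos0[1L])
        a_j <- min(a_j, sqrt(sum(pos0^2)) + 0.5)
        d_ms[j] <- saccade_duration_ms(a_j, kin)
        v_peak[j] <- kin$main_sequence_slope * a_j^kin$main_sequence_exponent
        amp[j] <- a_j
      }
      i1 <- min(i0 + d_ms[j] - 1L, n)
      prof <- raised_cosine_profile(a_j, d_ms[j])[seq_len(i1 - i0 + 1L)]
      add_x[i0:i1] <- add_x[i0:i1] + cos(theta) * prof
      add_y[i0:i1] <- add_y[i0:i1] + sin(theta) * prof
      if (i1 < n) {
        add_x[(i1 + 1L):n] <- add_x[(i1 + 1L):n] + cos(theta) * a_j
        add_y[(i1 + 1L):n] <- add_y[(i1 + 1L):n] + sin(theta) * a_j
      }
      cum_x <- cum_x + cos(theta) * a_j
      cum_y <- cum_y + sin(theta) * a_j
      rows[[j]] <- tibble(
        trial_id = tr$trial_id, subject = tr$subject, type = "saccade",
        onset_ms = t_rel[i0], offset_ms = t_rel[i1],
        amplitude = a_j, peak_velocity = v_peak[j],
        in_window = t_rel[i0] >= -300 & t_rel[i0] < 0
      )
    }
    px <- px + add_x; py <- py + add_y
    truth <- bind_rows(rows)
  }

  # --- per-eye measurement noise --------------------------------------
  xl <- px - 0.03 + rnorm(n, 0, kin$noise_sd)
  xr <- px + 0.03 + rnorm(n, 0, kin$noise_sd)
  yl <- py + rnorm(n, 0, kin$noise_sd)
  yr <- py + rnorm(n, 0, kin$noise_sd)

  # --- pupil + blinks --------------------------------------------------
  # pupil fluctuations: a modest slow component shared between the eyes
  # (arousal-linked co-dilation) plus a larger independent measurement
  # component per eye, so only genuine blinks deviate binocularly
  ar1 <- function(sd, a) {
    as.numeric(stats::filter(rnorm(n, 0, sd), a, method = "recursive")) *
      sqrt(1 - a^2)
  }
  shared <- ar1(0.5 * kin$pupil_noise_sd, 0.99)
  pl <- kin$pupil_baseline + shared + ar1(kin$pupil_noise_sd, 0.9)
  pr <- kin$pupil_baseline + shared + ar1(kin$pupil_noise_sd, 0.9)
  n_blinks <- rpois(1L, kin$blink_rate * n / 60000)
  if (n_blinks > 0) {
    for (b in seq_len(n_blinks)) {
      dur <- round(runif(1, kin$blink_duration_ms[1L], kin$blink_duration_ms[2L]))
      on <- sample.int(max(n - dur - 40L, 1L), 1L) + 20L
      ramp <- 20L
      core <- on:min(on + dur - 1L, n)
      down <- max(on - ramp, 1L):(on - 1L)
      frac_d <- seq_along(down) / length(down)
      pl[down] <- pl[down] * rev(frac_d); pr[down] <- pr[down] * rev(frac_d)
      pl[core] <- 0; pr[core] <- 0
      xl[core] <- NA; yl[core] <- NA; xr[core] <- NA; yr[core] <- NA
      core_end <- core[length(core)]
      if (core_end < n) {
        up <- (core_end + 1L):min(core_end + ramp, n)
        frac_u <- seq_along(up) / length(up)
        pl[up] <- pl[up] * frac_u; pr[up] <- pr[up] * frac_u
      }
      truth <- bind_rows(truth, tibble(
        trial_id = tr$trial_id, subject = tr$subject, type = "blink",
        onset_ms = t_rel[on], offset_ms = t_rel[core[length(core)]],
        amplitude = NA_real_, peak_velocity = NA_real_,
        in_window = t_rel[on] < 0 & t_rel[core[length(core)]] >= -300
      ))
    }
  }

  list(
    samples = tibble(
      subject = tr$subject,
      trial_id = tr$trial_id,
      time_ms = tr$target_onset_ms + t_rel,
      xL_deg = xl, yL_deg = yl, xR_deg = xr, yR_deg = yr,
      pupL = pl, pupR = pr
    ),
    truth = truth
  )
}

#' Simulate a two-group variable-foreperiod cohort at trial level
#'
#' Convenience wrapper producing the study-scale design: one uniform and
#' one inverse-U distribution group with `n_per_group` subjects each,
#' planted window-saccade ground truth, and the analysis columns
#' (`sfd`, `saccade_present`, exclusion flags) filled from the planted
#' truth. No gaze is synthesized; use [synthesize_gaze()] when the signal
#' path is under study.
#'
#' @param n_per_group Subjects per distribution group.
#' @param blocks,n_trials_per_block Block structure per subject.
#' @param model A [planted_model()].
#' @param seed Integer seed.
#' @return A trial tibble ready for [fit_experiment1()].
#' @export
simulate_exp1_cohort <- function(n_per_group = 20, blocks = 10,
                                 n_trials_per_block = 140,
                                 model = planted_model(), seed = 1) {
  du <- design_spec("exp1", "uniform", n_subjects = n_per_group,
                    blocks = blocks, n_trials_per_block = n_trials_per_block)
  di <- design_spec("exp1", "inverse_u", n_subjects = n_per_group,
                    blocks = blocks, n_trials_per_block = n_trials_per_block)
  tu <- sample_trial_sequence(du, seed = child_seed(seed, 11L))
  ti <- sample_trial_sequence(di, seed = child_seed(seed, 12L))
  ti$subject <- sub("^s", "t", ti$subject)
  tr <- bind_rows(tu, ti)
  tr$trial_id <- seq_len(nrow(tr))
  pl <- plant_window_saccades(tr, model, seed = child_seed(seed, 13L))
  pl %>%
    mutate(
      sfd = .data$sfd_true,
      prev_foreperiod_ms = .data$foreperiod_ms - .data$fp_difference_ms,
      saccade_present = if_else(.data$first_of_session, NA,
                                .data$saccade_window),
      excluded = .data$first_of_session,
      exclusion_reason = if_else(.data$first_of_session, "first_trial", "none")
    )
}
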