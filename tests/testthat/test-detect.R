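test_that("the 5-point velocity stencil is exact on constants and ramps", {
  v0 <- compute_velocity(rep(0.3, 100), rep(-0.1, 100))
  expect_true(all(v0$vx[3:98] == 0) && all(v0$vy[3:98] == 0))
  expect_true(all(is.na(v0$vx[c(1, 2, 99, 100)])))

  # 1 deg/s ramp in x: stencil returns exactly (1, 0) at interior samples
  t <- seq(0, 0.099, by = 0.001)
  vr <- compute_velocity(t * 1, rep(0, 100))
  expect_equal(vr$vx[3:98], rep(1, 96), tolerance = 1e-9)
  expect_equal(vr$vy[3:98], rep(0, 96))
})

test_that("measured peak velocity tracks the planted analytic profile", {
  kin <- kinematics_spec(drift_sd = 0, noise_sd = 0, background_rate = 0,
                         blink_rate = 0, amplitude_meanlog = log(0.5),
                         amplitude_sdlog = 0)
  tr <- make_small_exp1(n_subjects = 1, n_trials = 4, seed = 31)
  tr$saccade_window <- TRUE
  g <- synthesize_gaze(tr, kin, seed = 32)
  seg <- segment_gaze(g$samples, tr)
  for (id in tr$trial_id) {
    s <- seg[seg$trial_id == id, ]
    v <- compute_velocity(s$xL_deg, s$yL_deg)
    vmax <- max(sqrt(v$vx^2 + v$vy^2), na.rm = TRUE)
    truth <- g$truth$peak_velocity[g$truth$trial_id == id]
    expect_lt(abs(vmax - truth) / truth, 0.10)
  }
})

test_that("velocity thresholding flags pulses, not noise", {
  # pure Gaussian noise at lambda = 6: flagged fraction < 0.1%
  flagged <- 0L; total <- 0L
  for (s in 1:10) {
    set.seed(s)
    vx <- rnorm(5000); vy <- rnorm(5000)
    fl <- velocity_threshold(vx, vy, lambda = 6)
    flagged <- flagged + sum(fl); total <- total + length(fl)
  }
  expect_lt(flagged / total, 0.001)

  # one 20-sigma pulse: flagged run covers the pulse
  set.seed(99)
  vx <- rnorm(2000); vy <- rnorm(2000)
  vx[800:820] <- 20
  fl <- velocity_threshold(vx, vy)
  expect_true(all(fl[800:820]))
  expect_lt(sum(fl[-(795:825)]), 5)

  # constant velocity: degenerate segment
  expect_error(velocity_threshold(rep(1, 100), rep(1, 100)),
               class = "oseq_degenerate_segment")
})

test_that("candidate extraction enforces duration and intersaccadic rules", {
  t <- 0:999
  p <- detection_params()
  mkflags <- function(times) { f <- t %in% times; f }

  expect_equal(nrow(extract_monocular_saccades(mkflags(100:103), t, p)), 0)
  expect_equal(nrow(extract_monocular_saccades(mkflags(100:105), t, p)), 1)

  # two 10-sample runs separated by 20 ms: second discarded as overshoot
  two_close <- mkflags(c(100:109, 130:139))
  out <- extract_monocular_saccades(two_close, t, p)
  expect_equal(nrow(out), 1)
  expect_equal(out$onset_ms, 100)

  # separated by 80 ms: both kept
  two_far <- mkflags(c(100:109, 190:199))
  expect_equal(nrow(extract_monocular_saccades(two_far, t, p)), 2)

  # candidates intersecting exclusion intervals are discarded
  excl <- cbind(185, 260)
  out2 <- extract_monocular_saccades(two_far, t, p, exclude = excl)
  expect_equal(out2$onset_ms, 100)
})

test_that("binocular merging pairs overlapping candidates once", {
  cand <- function(on, off) {
    tibble::tibble(i_on = on + 1L, i_off = off + 1L, onset_ms = on,
                   offset_ms = off, amplitude = 0.5, peak_velocity = 30)
  }
  expect_equal(nrow(binocular_merge(cand(100, 130), cand(100, 130)[0, ])), 0)

  same <- binocular_merge(cand(100, 130), cand(100, 130))
  expect_equal(same$onset_ms, 100)
  expect_equal(same$offset_ms, 130)

  shifted <- binocular_merge(cand(100, 130), cand(110, 140))
  expect_equal(shifted$onset_ms, 100)
  expect_equal(shifted$offset_ms, 140)

  # one-to-one: two left candidates cannot claim the same right candidate
  left2 <- dplyr::bind_rows(cand(100, 130), cand(131, 160))
  right1 <- cand(105, 158)
  expect_equal(nrow(binocular_merge(left2, right1)), 1)
})

test_that("detection recovers planted events with valid kinematics", {
  scores <- list()
  for (s in 1:5) {
    tr <- make_small_exp1(n_subjects = 1, n_trials = 10, seed = 40 + s)
    res <- run_detection(tr, kinematics_spec(blink_rate = 0), seed = 60 + s)
    scores[[s]] <- detection_scores(res$saccades, res$gaze$truth)
    # exhaustive structural invariants on the output
    for (id in unique(res$saccades$trial_id)) {
      ev <- res$saccades[res$saccades$trial_id == id, ]
      expect_true(all(ev$offset_ms - ev$onset_ms >= 5))
      if (nrow(ev) > 1) {
        expect_true(all(ev$onset_ms[-1] - ev$offset_ms[-nrow(ev)] >= 50))
      }
    }
  }
  expect_true(all(vapply(scores, `[[`, numeric(1), "recall") >= 0.9))
  expect_true(all(vapply(scores, `[[`, numeric(1), "precision") >= 0.9))
})

test_that("detected amplitudes track planted amplitudes", {
  tr <- make_small_exp1(n_subjects = 1, n_trials = 15, seed = 51)
  res <- run_detection(tr, kinematics_spec(blink_rate = 0), seed = 52)
  truth <- res$gaze$truth[res$gaze$truth$type == "saccade", ]
  rel_err <- c()
  for (i in seq_len(nrow(truth))) {
    ev <- res$saccades[res$saccades$trial_id == truth$trial_id[i], ]
    j <- which(abs(ev$onset_ms - truth$onset_ms[i]) <= 10)
    if (length(j)) {
      rel_err <- c(rel_err, abs(ev$amplitude[j[1]] - truth$amplitude[i]) /
                     truth$amplitude[i])
    }
  }
  expect_gt(length(rel_err), 20)
  expect_lt(median(rel_err), 0.2)
})

test_that("detection is invariant to constant position offsets", {
  tr <- make_small_exp1(n_subjects = 1, n_trials = 6, seed = 53)
  g <- synthesize_gaze(tr, kinematics_spec(blink_rate = 0), seed = 54)
  seg <- segment_gaze(g$samples, tr) |> lowpass_filter()
  shifted <- seg
  for (ch in c("xL_deg", "yL_deg", "xR_deg", "yR_deg")) {
    shifted[[ch]] <- shifted[[ch]] + 3
  }
  s1 <- detect_saccades(seg)
  s2 <- detect_saccades(shifted)
  expect_equal(s1$onset_ms, s2$onset_ms)
  expect_equal(s1$amplitude, s2$amplitude, tolerance = 1e-9)
})

test_that("main-sequence QC separates lawful from shuffled kinematics", {
  set.seed(7)
  amp <- rlnorm(60, -1, 0.6)
  events <- tibble::tibble(trial_id = 1L, amplitude = amp,
                           peak_velocity = 55 * amp^1.1)
  trials <- tibble::tibble(trial_id = 1L, subject = "s01")
  ms <- main_sequence_check(events, trials)
  expect_equal(ms$r, 1)
  expect_true(ms$pass)

  shuffled <- events
  shuffled$peak_velocity <- sample(shuffled$peak_velocity)
  ms2 <- main_sequence_check(shuffled, trials)
  expect_lt(abs(ms2$r), 0.5)
  expect_false(ms2$pass)

  few <- main_sequence_check(events[1:5, ], trials)
  expect_true(is.na(few$pass))
})
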