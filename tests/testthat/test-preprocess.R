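test_that("pixel-to-degree conversion matches trigonometry", {
  expect_equal(as.numeric(pixels_to_degrees(960.5, 540.5)), c(0, 0))

  # 1 cm offset at 100 cm: atan(1/100) in degrees, along each axis
  g <- screen_geometry()
  px_per_cm_x <- g$screen_px[1] / g$screen_cm[1]
  off <- pixels_to_degrees(960.5 + px_per_cm_x, 540.5)
  expect_equal(off$x_deg, atan(1 / 100) * 180 / pi, tolerance = 1e-10)
  expect_equal(off$x_deg, 0.5729, tolerance = 1e-4)

  # one pixel at default geometry ~ 0.015847 degrees
  one_px <- pixels_to_degrees(961.5, 540.5)$x_deg
  expect_equal(one_px, atan((53.1 / 1920) / 100) * 180 / pi, tolerance = 1e-12)
  expect_equal(one_px, 0.01585, tolerance = 1e-3)

  expect_error(screen_geometry(distance_cm = 0), "positive")
})

test_that("low-pass filtering passes low frequencies and rejects high ones", {
  t <- seq(0, 1.999, by = 0.001)
  mk <- function(x) tibble::tibble(xL_deg = x, yL_deg = x, xR_deg = x,
                                   yR_deg = x)
  amp_ratio <- function(f_hz) {
    x <- sin(2 * pi * f_hz * t)
    out <- lowpass_filter(mk(x), cutoff = 60)$xL_deg
    core <- 301:1700   # away from segment edges
    max(abs(out[core])) / 1
  }
  # constant signal unchanged
  const <- lowpass_filter(mk(rep(0.7, 2000)))$xL_deg
  expect_lt(max(abs(const - 0.7)), 1e-9)
  # 10 Hz: < 1% attenuation; 200 Hz: > 90% attenuation
  expect_gt(amp_ratio(10), 0.99)
  expect_lt(amp_ratio(200), 0.10)
  expect_error(lowpass_filter(mk(t), cutoff = 500), "Nyquist")
})

test_that("filtering is per contiguous run and near-idempotent in band", {
  t <- seq(0, 1.999, by = 0.001)
  x <- sin(2 * pi * 10 * t)
  x[800:900] <- NA
  df <- tibble::tibble(xL_deg = x, yL_deg = x, xR_deg = x, yR_deg = x)
  once <- lowpass_filter(df)
  twice <- lowpass_filter(once)
  expect_identical(is.na(once$xL_deg), is.na(x))
  core <- c(301:700, 1100:1700)
  expect_lt(max(abs(twice$xL_deg[core] - once$xL_deg[core])),
            0.01 * max(abs(once$xL_deg[core])))
  # a run shorter than the warm-up is passed through with a message
  y <- rep(0.2, 20)
  short <- tibble::tibble(xL_deg = y, yL_deg = y, xR_deg = y, yR_deg = y)
  expect_message(out <- lowpass_filter(short), "warm-up")
  expect_identical(out$xL_deg, y)
})

test_that("segmentation spans cue-500 to target+500 and conserves samples", {
  tr <- make_small_exp1(n_subjects = 2, n_trials = 8, seed = 21)
  g <- synthesize_gaze(tr, kinematics_spec(blink_rate = 0), seed = 22)
  seg <- segment_gaze(g$samples, tr)
  n_per_trial <- table(seg$trial_id)
  expect_equal(unname(as.integer(n_per_trial)),
               as.integer(tr$foreperiod_ms + 1000))
  expect_equal(nrow(seg), nrow(g$samples))   # simulator emits segments only
  rng <- tapply(seg$t_rel, seg$trial_id, range)
  for (id in tr$trial_id) {
    expect_equal(rng[[as.character(id)]],
                 c(-(tr$foreperiod_ms[tr$trial_id == id] + 500), 499))
  }
})

test_that("blink detection requires a binocular pupil deviation", {
  base_t <- 0:2299 - 1800
  mkseg <- function(pupL, pupR, xL = 0, xR = 0) {
    tibble::tibble(trial_id = 1L, t_rel = base_t,
                   xL_deg = xL, yL_deg = 0, xR_deg = xR, yR_deg = 0,
                   pupL = pupL, pupR = pupR)
  }
  # constant pupil, no gaps: nothing to find (pupil criterion skipped)
  expect_message(out <- detect_blinks(mkseg(rep(1000, 2300), rep(1000, 2300))),
                 "skipped")
  expect_equal(nrow(out), 0)

  # monocular deviation only: still nothing (binocular requirement)
  set.seed(1)
  pl <- 1000 + rnorm(2300); pr <- 1000 + rnorm(2300)
  pl[1200:1260] <- pl[1200:1260] + 50
  expect_equal(nrow(detect_blinks(mkseg(pl, pr))), 0)
})

test_that("binocular pupil excursions are padded into exclusion intervals", {
  # excursion spanning t = -800..-720; detected interval padded +-200 ms
  set.seed(2)
  t <- 0:2299 - 1800
  pl <- 1000 + rnorm(2300); pr <- 1000 + rnorm(2300)
  hit <- t >= -800 & t <= -720
  pl[hit] <- pl[hit] + 300; pr[hit] <- pr[hit] + 300
  seg <- tibble::tibble(trial_id = 1L, t_rel = t, xL_deg = 0, yL_deg = 0,
                        xR_deg = 0, yR_deg = 0, pupL = pl, pupR = pr)
  out <- detect_blinks(seg)
  expect_equal(nrow(out), 1)
  expect_equal(out$onset_ms, -800)
  expect_equal(out$offset_ms, -720)
  expect_equal(out$excl_onset_ms, -1000)
  expect_equal(out$excl_offset_ms, -520)

  # brute-force scan oracle over the same segment
  dl <- abs(pl - mean(pl)) > 2.5 * sd(pl)
  dr <- abs(pr - mean(pr)) > 2.5 * sd(pr)
  runs <- rle(dl & dr)
  expect_true(any(runs$values & runs$lengths >= 3))

  # padding clips to segment bounds
  pl2 <- 1000 + rnorm(2300); pr2 <- 1000 + rnorm(2300)
  pl2[1:80] <- 0; pr2[1:80] <- 0
  seg2 <- seg
  seg2$pupL <- pl2; seg2$pupR <- pr2
  out2 <- detect_blinks(seg2)
  expect_equal(out2$excl_onset_ms[1], t[1])
})

test_that("planted blinks are recovered on simulator output", {
  tr <- make_small_exp1(n_subjects = 2, n_trials = 25, seed = 23)
  kin <- kinematics_spec(blink_rate = 20)  # blink-rich for this check
  g <- synthesize_gaze(tr, kin, seed = 24)
  seg <- segment_gaze(g$samples, tr)
  bl <- detect_blinks(seg)
  planted <- g$truth[g$truth$type == "blink", ]
  expect_gt(nrow(planted), 10)
  jacc <- vapply(seq_len(nrow(planted)), function(i) {
    b <- bl[bl$trial_id == planted$trial_id[i], , drop = FALSE]
    if (!nrow(b)) return(0)
    inter <- pmax(0, pmin(b$offset_ms, planted$offset_ms[i]) -
                     pmax(b$onset_ms, planted$onset_ms[i]))
    un <- pmax(b$offset_ms, planted$offset_ms[i]) -
      pmin(b$onset_ms, planted$onset_ms[i])
    max(inter / un)
  }, numeric(1))
  expect_gte(mean(jacc >= 0.5), 0.95)
})
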