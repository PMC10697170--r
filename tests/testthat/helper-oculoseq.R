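# Shared fixtures and independent oracles for the test suite.

# Small exp1 simulation: trial table with planted window-saccade truth.
make_small_exp1 <- function(n_subjects = 2, blocks = 1, n_trials = 20,
                            distribution = "uniform",
                            model = planted_model(), seed = 1) {
  d <- design_spec("exp1", distribution, n_subjects = n_subjects,
                   blocks = blocks, n_trials_per_block = n_trials)
  tr <- sample_trial_sequence(d, seed = seed)
  plant_window_saccades(tr, model, seed = seed + 1000L)
}

# Trial-level planted dataset at arbitrary scale, both distribution groups,
# no gaze synthesis (for inference tests).
make_planted_groups <- function(n_per_group = 4, blocks = 1, n_trials = 50,
                                model = planted_model(), seed = 1) {
  du <- design_spec("exp1", "uniform", n_subjects = n_per_group,
                    blocks = blocks, n_trials_per_block = n_trials)
  di <- design_spec("exp1", "inverse_u", n_subjects = n_per_group,
                    blocks = blocks, n_trials_per_block = n_trials)
  tu <- sample_trial_sequence(du, seed = seed)
  ti <- sample_trial_sequence(di, seed = seed + 1L)
  ti$subject <- sub("^s", "t", ti$subject)
  tr <- dplyr::bind_rows(tu, ti)
  tr$trial_id <- seq_len(nrow(tr))
  plant_window_saccades(tr, model, seed = seed + 2L)
}

# Planted truth -> analysis columns, bypassing gaze synthesis/detection.
truth_as_trials <- function(planted) {
  planted$saccade_present <- ifelse(planted$first_of_session, NA,
                                    planted$saccade_window)
  planted$excluded <- planted$first_of_session
  planted$exclusion_reason <- ifelse(planted$first_of_session,
                                     "first_trial", "none")
  planted$sfd <- planted$sfd_true
  planted$prev_foreperiod_ms <- planted$foreperiod_ms - planted$fp_difference_ms
  planted
}

# Exp2 planted table -> analysis columns (previous foreperiod via the
# presented-trial sequence; no gaze involved).
truth_via_columns <- function(planted) {
  planted <- planted[order(planted$subject, planted$session, planted$block,
                           planted$trial), ]
  prev <- ave(planted$foreperiod_ms, planted$subject,
              FUN = function(x) c(NA, x[-length(x)]))
  planted$prev_foreperiod_ms <- ifelse(planted$first_of_session, NA, prev)
  planted$saccade_present <- ifelse(planted$first_of_session, NA,
                                    planted$saccade_window)
  planted$excluded <- planted$first_of_session
  planted
}

# Brute-force Benjamini-Hochberg step-up: q_i = min over j >= rank(i) of
# min(1, m * p_(j) / j).
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(o == i)
    cand <- vapply(rank_i:m, function(j) min(1, m * p[o[j]] / j), numeric(1))
    q[i] <- min(cand)
  }
  q
}

# Independent two-pass Cousineau-Morey SEs on a subjects x conditions matrix.
cousineau_morey_oracle <- function(m, morey = TRUE) {
  m <- m[stats::complete.cases(m), , drop = FALSE]
  J <- ncol(m); n <- nrow(m)
  z <- matrix(NA_real_, n, J)
  grand <- mean(m)
  for (i in seq_len(n)) for (j in seq_len(J)) {
    z[i, j] <- m[i, j] - mean(m[i, ]) + grand
  }
  out <- numeric(J)
  for (j in seq_len(J)) {
    out[j] <- stats::sd(z[, j]) * (if (morey) sqrt(J / (J - 1)) else 1) / sqrt(n)
  }
  out
}

# Maximum-likelihood logistic regression via direct optimization of the
# hand-written log-likelihood (independent of glm's IRLS).
logistic_ml_oracle <- function(X, y) {
  nll <- function(b) {
    eta <- as.numeric(X %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  fit <- stats::optim(rep(0, ncol(X)), nll, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  fit$par
}

# Match detected saccades to planted ground truth by onset proximity.
detection_scores <- function(saccades, truth, tol_ms = 10) {
  truth <- truth[truth$type == "saccade", , drop = FALSE]
  hit_truth <- vapply(seq_len(nrow(truth)), function(i) {
    on <- saccades$onset_ms[saccades$trial_id == truth$trial_id[i]]
    length(on) > 0 && any(abs(on - truth$onset_ms[i]) <= tol_ms)
  }, logical(1))
  hit_det <- vapply(seq_len(nrow(saccades)), function(i) {
    on <- truth$onset_ms[truth$trial_id == saccades$trial_id[i]]
    length(on) > 0 && any(abs(on - saccades$onset_ms[i]) <= tol_ms)
  }, logical(1))
  list(recall = mean(hit_truth), precision = mean(hit_det),
       n_truth = nrow(truth), n_detected = nrow(saccades))
}

# Run simulation -> preprocessing -> detection for detection-quality tests.
run_detection <- function(planted, kin = kinematics_spec(), seed = 1,
                          use_blinks = TRUE) {
  g <- synthesize_gaze(planted, kin, seed = seed)
  seg <- suppressMessages(lowpass_filter(segment_gaze(g$samples, planted)))
  bl <- detect_blinks(seg)
  sac <- detect_saccades(seg, if (use_blinks) bl else NULL)
  list(gaze = g, segments = seg, blinks = bl, saccades = sac)
}
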