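test_that("contrast matrices implement sum, difference and treatment coding", {
  expect_equal(unname(build_contrasts(c("a", "b"), "sum")),
               matrix(c(1, -1), 2, 1))
  expect_equal(unname(build_contrasts(c("a", "b", "c"), "treatment")),
               matrix(c(0, 1, 0, 0, 0, 1), 3, 2))
  expect_error(build_contrasts("a", "sum"), "2 levels")

  # difference coding: coefficients recover successive level differences.
  # Matrix-algebra oracle: mu = b0 + C b  =>  b = solve on the full basis.
  mu <- c(0.2, 0.5, 0.45, 0.8, 0.75)
  C <- build_contrasts(as.character(1:5), "difference")
  X <- cbind(1, C)
  b <- solve(t(X) %*% X, t(X) %*% mu)
  expect_equal(as.numeric(b[-1]), diff(mu), tolerance = 1e-12)
})

test_that("FDR adjustment equals the brute-force step-up definition", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.3), 0.3)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(10)
  for (k in 1:40) {
    p <- round(runif(sample(1:10, 1)), 3)
    q <- fdr_adjust(p)
    expect_equal(q, bh_bruteforce(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("the BIC Bayes factor follows its closed form", {
  fake <- function(bic, n = 100) {
    structure(list(bic = bic, n_obs = n), class = "oseq_fit")
  }
  expect_equal(bf01_bic(fake(500), fake(500)), 1)
  expect_equal(bf01_bic(fake(500 + 2 * log(10)), fake(500)), 10)
  expect_equal(bf01_bic(fake(500 - 2 * log(10)), fake(500)), 0.1)
  expect_error(bf01_bic(fake(500, 100), fake(500, 101)), "identical data")
})

test_that("without random effects the fit equals a direct ML oracle", {
  set.seed(20)
  n <- 400
  d <- tibble::tibble(x = rnorm(n), subject = rep(c("a", "b"), n / 2))
  d$y <- rbinom(n, 1, plogis(-0.5 + 0.8 * d$x))
  fit <- fit_glmm(d, y ~ x, random = "none")
  X <- cbind(1, d$x)
  oracle <- logistic_ml_oracle(X, d$y)
  expect_equal(unname(fit$coefficients), oracle, tolerance = 1e-6)
  expect_equal(fit$bic, -2 * fit$loglik + 2 * log(n), tolerance = 1e-9)
  expect_error(fit_glmm(d, x ~ y, random = "none"), "binary")
})

test_that("an intercept-only mixed fit recovers the marginal log-odds", {
  d <- truth_as_trials(make_small_exp1(
    n_subjects = 4, n_trials = 300,
    model = planted_model(beta0 = -1, beta_lin = 0, beta_quad = 0,
                          beta_dist = 0, beta_dist_lin = 0,
                          beta_dist_quad = 0, subject_sd_intercept = 0,
                          subject_sd_slope = 0),
    seed = 71))
  d <- d[!d$excluded, ]
  fit <- fit_glmm(d, saccade_present ~ 1, random = "(1 | subject)")
  se <- sqrt(fit$vcov[1, 1])
  expect_lt(abs(fit$coefficients[[1]] - (-1)), 3 * max(se, 0.05))
  expect_true(fit$singular)  # zero planted between-subject variance
})

test_that("Type-II LR tests drop the right terms and report honest df", {
  d <- truth_as_trials(make_planted_groups(n_per_group = 3, n_trials = 120,
                                           seed = 72))
  d <- d[!d$excluded, ]
  d$distribution <- factor(d$distribution, levels = c("uniform", "inverse_u"))
  stats::contrasts(d$distribution) <- build_contrasts(levels(d$distribution),
                                                      "sum")
  fixed <- saccade_present ~ sfd + I(sfd^2) + distribution +
    sfd:distribution + I(sfd^2):distribution
  lt <- lr_test_type2(d, fixed, c("sfd", "I(sfd^2)"), random = "none")
  expect_equal(lt$df, 2)
  # interactions containing sfd are excluded from both models
  expect_false(any(grepl(":", attr(terms(lt$fit_full$formula),
                                   "term.labels"))))
  lt2 <- lr_test_type2(d, fixed, "distribution", random = "none")
  expect_equal(lt2$df, 1)
  expect_error(lr_test_type2(d, fixed, "nonexistent", random = "none"),
               "not in model")

  # testing a term against itself: chi-square 0, p = 1
  same <- lr_test_type2(d, saccade_present ~ 1, character(0), random = "none")
  expect_equal(same$df, 0)
  expect_equal(same$p, 1)
})

test_that("LR statistics are invariant to the tested factor's coding", {
  d <- truth_as_trials(make_planted_groups(n_per_group = 3, n_trials = 100,
                                           seed = 73))
  d <- d[!d$excluded, ]
  d$distribution <- factor(d$distribution, levels = c("uniform", "inverse_u"))
  fixed <- saccade_present ~ sfd + distribution
  chis <- vapply(c("sum", "treatment", "difference"), function(cd) {
    stats::contrasts(d$distribution) <- build_contrasts(levels(d$distribution), cd)
    lr_test_type2(d, fixed, "distribution", random = "none")$chisq
  }, numeric(1))
  expect_lt(max(chis) - min(chis), 1e-8)
})

test_that("the random-effects ladder keeps real slopes and trims null ones", {
  mk <- function(sd_slope, seed) {
    truth_as_trials(make_small_exp1(
      n_subjects = 24, n_trials = 120,
      model = planted_model(beta_dist = 0, beta_dist_lin = 0,
                            beta_dist_quad = 0,
                            subject_sd_intercept = 0.6,
                            subject_sd_slope = sd_slope),
      seed = seed))
  }
  fixed <- saccade_present ~ sfd + I(sfd^2)

  d_big <- mk(0.8, 81)
  d_big <- d_big[!d_big$excluded, ]
  sel_big <- select_random_structure(d_big, fixed, slope_terms = "sfd")
  expect_match(sel_big$random, "sfd")
  expect_true(any(sel_big$log$accepted & grepl("sfd", sel_big$log$structure)))

  d_null <- mk(0, 82)
  d_null <- d_null[!d_null$excluded, ]
  sel_null <- select_random_structure(d_null, fixed, slope_terms = "sfd")
  expect_equal(sel_null$random, "(1 | subject)")
  expect_true(any(!sel_null$log$accepted))
})

test_that("categorical SFD contrasts recover the planted sign pattern", {
  d <- truth_as_trials(make_planted_groups(
    n_per_group = 6, n_trials = 400,
    model = planted_model(beta_lin = -0.5, beta_quad = 0, beta_dist = 0,
                          beta_dist_lin = 0, beta_dist_quad = 0,
                          subject_sd_intercept = 0.3, subject_sd_slope = 0),
    seed = 83))
  ct <- categorical_sfd_contrasts(d, random = "(1 | subject)")
  expect_equal(nrow(ct), 8)
  expect_false("0" %in% ct$label)
  lev <- as.numeric(ct$label)
  # planted monotone negative linear effect: negative levels above zero,
  # positive levels below (sign check against planted truth)
  expect_true(all(ct$estimate[lev < 0] > 0))
  expect_true(all(ct$estimate[lev > 0] < 0))
  expect_true(all(ct$p_fdr >= ct$p_raw - 1e-12))
  expect_true(all(ct$ci_low <= ct$estimate & ct$estimate <= ct$ci_high))
})

test_that("a single-contrast family is not FDR-penalized", {
  fake <- structure(list(coefficients = c(a = 0.4),
                         vcov = matrix(0.04, 1, 1, dimnames = list("a", "a"))),
                    class = "oseq_fit")
  out <- oculoseq:::wald_contrast_table(fake, matrix(1, 1, 1,
                                                     dimnames = list(NULL, "a")),
                                        "only")
  expect_equal(out$p_fdr, out$p_raw)
  expect_equal(out$z_ratio, 2)
})

test_that("the condition/foreperiod model detects planted structure", {
  d2 <- design_spec("exp2", n_subjects = 12, n_trials_per_block = 60)
  tr <- sample_trial_sequence(d2, seed = 91)
  # strong condition effect (lower odds in fixed blocks)
  pl <- plant_condition_saccades(tr, beta_condition = -0.4,
                                 subject_sd_intercept = 0.3,
                                 subject_sd_slope = 0, seed = 92)
  pl <- truth_via_columns(pl)
  f1 <- fit_experiment2(pl)
  expect_lt(f1$tests$p[f1$tests$term == "condition"], 0.05)

  # opposite-sign foreperiod slopes per condition: interaction detected
  pl2 <- plant_condition_saccades(tr, beta_condition = 0, beta_foreperiod = 0,
                                  beta_interaction = 0.5,
                                  subject_sd_intercept = 0.3,
                                  subject_sd_slope = 0, seed = 93)
  pl2 <- truth_via_columns(pl2)
  f2 <- fit_experiment2(pl2)
  expect_lt(f2$tests$p[f2$tests$term == "condition:fp"], 0.01)

  # screening: analyzed random-block trials have matching n-1 foreperiod
  rnd <- f2$data[f2$data$condition == "random", ]
  expect_true(all(rnd$prev_foreperiod_ms == rnd$foreperiod_ms))

  # planted zero foreperiod effect: non-significant with BF01 favoring null
  pl3 <- plant_condition_saccades(tr, beta_condition = -0.2,
                                  beta_foreperiod = 0, beta_interaction = 0,
                                  subject_sd_intercept = 0.3,
                                  subject_sd_slope = 0, seed = 94)
  pl3 <- truth_via_columns(pl3)
  f3 <- fit_experiment2(pl3)
  expect_gt(f3$tests$p[f3$tests$term == "fp"], 0.05)
  expect_gt(f3$tests$bf01[f3$tests$term == "fp"], 1)

  glanced <- glance(f2)
  expect_true(is.numeric(glanced$BIC))
  tidied <- tidy(f2)
  expect_true(all(c("term", "estimate", "std.error") %in% names(tidied)))
})
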