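# Analysis-ready subset: included trials with a defined response.
analysis_subset <- function(trials, need_sfd = TRUE) {
  out <- trials
  if ("excluded" %in% names(out)) out <- filter(out, !.data$excluded)
  out <- filter(out, !is.na(.data$saccade_present))
  if (need_sfd) out <- filter(out, !is.na(.data$sfd))
  out
}

# Distribution factor with sum coding (+1 uniform, -1 inverse-U).
code_distribution <- function(trials) {
  f <- factor(trials$distribution, levels = c("uniform", "inverse_u"))
  stats::contrasts(f) <- build_contrasts(levels(f), "sum")
  f
}

#' Fit the sequential-effect model (variable-foreperiod design)
#'
#' Fits the binomial-logit mixed model of pretarget saccade presence with
#' linear and quadratic standardized-foreperiod-difference (SFD) terms,
#' the foreperiod-distribution factor (sum-coded), and their interactions,
#' with a by-subject random intercept and random SFD slope. Type-II
#' likelihood-ratio tests are reported per term family (SFD joint df 2,
#' distribution df 1, interaction joint df 2) together with the
#' BIC-approximated Bayes factor `BF01` for each comparison.
#'
#' @param trials Trial table from [build_trial_table()] (exp1 design).
#' @param random Random-effects structure string, or `"ladder"` to select
#'   it with [select_random_structure()].
#' @param ... Passed to [fit_glmm()].
#' @return An object of class `"oseq_exp_fit"`: list with `fit`
#'   (`oseq_fit`), `tests` (tibble: term, chisq, df, p, bf01), `random`,
#'   `selection_log` (when the ladder ran) and `data`.
#' @export
fit_experiment1 <- function(trials, random = "(1 + sfd | subject)", ...) {
  d <- analysis_subset(trials)
  if (dplyr::n_distinct(d$subject) < 2L) abort("Need >= 2 subjects.")
  d$distribution <- code_distribution(d)
  fixed <- saccade_present ~ sfd + I(sfd^2) + distribution +
    sfd:distribution + I(sfd^2):distribution
  sel_log <- NULL
  if (identical(random, "ladder")) {
    sel <- select_random_structure(d, fixed,
                                   slope_terms = c("sfd", "I(sfd^2)"), ...)
    random <- sel$random
    sel_log <- sel$log
  }
  fit <- fit_glmm(d, fixed, random = random, ...)
  fams <- list(
    sfd = c("sfd", "I(sfd^2)"),
    distribution = "distribution",
    `sfd:distribution` = c("sfd:distribution", "I(sfd^2):distribution")
  )
  tests <- purrr::imap(fams, function(labs, nm) {
    lt <- lr_test_type2(d, fixed, labs, random = random, ...)
    tibble(term = nm, chisq = lt$chisq, df = lt$df, p = lt$p,
           bf01 = bf01_bic(lt$fit_full, lt$fit_reduced))
  }) %>% bind_rows()
  structure(list(fit = fit, tests = tests, random = random,
                 selection_log = sel_log, data = d,
                 experiment = "exp1"),
            class = "oseq_exp_fit")
}

#' Fit the fixed-vs-random foreperiod model
#'
#' After screening random-block trials so that the previous foreperiod
#' equals the current one (see [screen_prev_equal()]), fits a
#' binomial-logit mixed model with condition (fixed/random, sum-coded),
#' foreperiod (continuous, centered, in seconds) and their interaction,
#' with a by-subject random intercept and random slopes for both main
#' effects. When that structure fails to converge or is singular, the
#' random-effects ladder trims it. With `categorical_fp = TRUE`,
#' foreperiod enters as a factor with successive-difference contrasts
#' instead. Type-II LR tests and `BF01` are reported per term.
#'
#' @param trials Trial table from [build_trial_table()] (exp2 design).
#' @param screen Apply the previous-foreperiod-equal screening rule.
#' @param categorical_fp Treat foreperiod as a factor with difference
#'   contrasts.
#' @param ... Passed to [fit_glmm()].
#' @return An `"oseq_exp_fit"` object (see [fit_experiment1()]).
#' @export
fit_experiment2 <- function(trials, screen = TRUE, categorical_fp = FALSE,
                            ...) {
  d <- trials
  if ("excluded" %in% names(d)) d <- filter(d, !.data$excluded)
  d <- filter(d, !is.na(.data$saccade_present))
  if (screen) d <- screen_prev_equal(d)
  if (dplyr::n_distinct(d$condition) < 2L) {
    abort("Fewer than 2 condition levels after screening.")
  }
  d$condition <- factor(d$condition, levels = c("fixed", "random"))
  stats::contrasts(d$condition) <- build_contrasts(levels(d$condition), "sum")
  if (categorical_fp) {
    lv <- sort(unique(d$foreperiod_ms))
    d$fp <- factor(d$foreperiod_ms, levels = lv)
    stats::contrasts(d$fp) <- build_contrasts(as.character(lv), "difference")
  } else {
    d$fp <- (d$foreperiod_ms - mean(d$foreperiod_ms)) / 1000
  }
  fixed <- saccade_present ~ condition + fp + condition:fp
  random <- "(1 + condition + fp | subject)"
  fit <- fit_glmm(d, fixed, random = random, ...)
  sel_log <- NULL
  if (!fit$converged || fit$singular) {
    sel <- select_random_structure(d, fixed,
                                   slope_terms = c("condition", "fp"), ...)
    fit <- sel$fit
    random <- sel$random
    sel_log <- sel$log
  }
  fams <- list(condition = "condition", fp = "fp",
               `condition:fp` = "condition:fp")
  tests <- purrr::imap(fams, function(labs, nm) {
    lt <- lr_test_type2(d, fixed, labs, random = random, ...)
    tibble(term = nm, chisq = lt$chisq, df = lt$df, p = lt$p,
           bf01 = bf01_bic(lt$fit_full, lt$fit_reduced))
  }) %>% bind_rows()
  structure(list(fit = fit, tests = tests, random = random,
                 selection_log = sel_log, data = d,
                 experiment = "exp2"),
            class = "oseq_exp_fit")
}

#' @export
print.oseq_exp_fit <- function(x, ...) {
  cat("<oseq_exp_fit> ", x$experiment, ", random: ", x$random, "\n", sep = "")
  print(as.data.frame(x$tests), row.names = FALSE)
  invisible(x)
}

#' @rdname fit_experiment1
#' @param x An `oseq_exp_fit`.
#' @exportS3Method generics::tidy
tidy.oseq_exp_fit <- function(x, ...) tidy(x$fit)

#' @rdname fit_experiment1
#' @exportS3Method generics::glance
glance.oseq_exp_fit <- function(x, ...) glance(x$fit)

#' Contrast every foreperiod-difference level against zero
#'
#' Refits the sequential-effect model with the foreperiod difference as a
#' categorical factor and reports, for every non-zero level, the Wald
#' contrast of that level minus the zero level (previous foreperiod equal
#' to the current one) on the log-odds scale, with 95% CIs, z-ratios and
#' Benjamini-Hochberg FDR-adjusted p-values (the family is the set of
#' non-zero levels).
#'
#' @param trials Trial table (exp1 design) from [build_trial_table()].
#' @param random Random-effects structure for the categorical refit.
#' @param ... Passed to [fit_glmm()].
#' @return A contrast tibble: `label`, `estimate`, `ci_low`, `ci_high`,
#'   `z_ratio`, `p_raw`, `p_fdr`.
#' @export
categorical_sfd_contrasts <- function(trials, random = "(1 | subject)", ...) {
  d <- analysis_subset(trials, need_sfd = FALSE)
  d <- filter(d, !is.na(.data$fp_difference_ms))
  lv <- sort(unique(d$fp_difference_ms))
  if (!0 %in% lv) abort("The zero foreperiod-difference level is missing.")
  d$sfd_cat <- factor(d$fp_difference_ms, levels = lv)
  d$sfd_cat <- stats::relevel(d$sfd_cat, ref = "0")
  fit <- fit_glmm(d, saccade_present ~ sfd_cat, random = random, ...)
  cn <- names(fit$coefficients)
  idx <- which(startsWith(cn, "sfd_cat"))
  L <- matrix(0, length(idx), length(cn), dimnames = list(NULL, cn))
  L[cbind(seq_along(idx), idx)] <- 1
  labels <- sub("^sfd_cat", "", cn[idx])
  out <- wald_contrast_table(fit, L, labels)
  out[order(as.numeric(out$label)), ]
}

#' Contrast foreperiod distributions at each foreperiod-difference level
#'
#' Refits the model with categorical foreperiod difference crossed with the
#' (sum-coded) distribution factor and reports, per level, the Wald
#' contrast uniform minus inverse-U on the log-odds scale, FDR-corrected
#' across levels.
#'
#' @inheritParams categorical_sfd_contrasts
#' @return A contrast tibble as in [categorical_sfd_contrasts()].
#' @export
distribution_by_sfd_contrasts <- function(trials, random = "(1 | subject)",
                                          ...) {
  d <- analysis_subset(trials, need_sfd = FALSE)
  d <- filter(d, !is.na(.data$fp_difference_ms))
  lv <- sort(unique(d$fp_difference_ms))
  d$sfd_cat <- factor(d$fp_difference_ms, levels = lv)
  d$distribution <- code_distribution(d)
  fit <- fit_glmm(d, saccade_present ~ sfd_cat * distribution,
                  random = random, ...)
  # design rows for each (level, distribution) cell, built with the fit's
  # own contrasts; contrast = uniform row minus inverse-U row
  grid <- tidyr::expand_grid(sfd_cat = factor(lv, levels = lv),
                             distribution = factor(c("uniform", "inverse_u"),
                                                   levels = c("uniform", "inverse_u")))
  stats::contrasts(grid$sfd_cat) <- stats::contrasts(d$sfd_cat)
  stats::contrasts(grid$distribution) <- stats::contrasts(d$distribution)
  X <- model.matrix(~ sfd_cat * distribution, grid)
  rows_u <- X[grid$distribution == "uniform", , drop = FALSE]
  rows_i <- X[grid$distribution == "inverse_u", , drop = FALSE]
  L <- rows_u - rows_i
  colnames(L) <- colnames(X)
  L <- L[, names(fit$coefficients), drop = FALSE]
  wald_contrast_table(fit, L, labels = as.character(lv))
}
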