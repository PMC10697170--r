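#' Within-subject-corrected standard errors
#'
#' Cousineau normalization with Morey's bias correction, for
#' repeated-measures error bars: each subject's scores are centered on the
#' subject mean and shifted back by the grand mean, the per-condition SD
#' of the normalized scores is scaled by `sqrt(J / (J - 1))` for `J`
#' conditions, and the SE is that SD divided by `sqrt(n_subjects)`.
#' Subjects with missing cells are dropped listwise. Set `morey = FALSE`
#' for plain Cousineau SEs.
#'
#' @param cellmeans A subjects x conditions matrix (or data frame) of
#'   per-subject condition means.
#' @param morey Apply the J/(J-1) bias correction.
#' @return A tibble with `condition`, `se`, `n_subjects`.
#' @export
within_subject_se <- function(cellmeans, morey = TRUE) {
  m0 <- as.matrix(cellmeans)
  J <- ncol(m0)
  if (J < 2L) abort("Need at least 2 conditions (J >= 2).")
  m <- m0[complete.cases(m0), , drop = FALSE]
  if (nrow(m) < 2L) {
    warn("Fewer than 2 complete subjects; within-subject SEs are NA.")
    return(tibble(condition = colnames(m0) %||% as.character(seq_len(J)),
                  se = NA_real_, n_subjects = nrow(m)))
  }
  grand <- mean(m)
  z <- m - rowMeans(m) + grand
  corr <- if (morey) sqrt(J / (J - 1)) else 1
  tibble(
    condition = colnames(m) %||% as.character(seq_len(J)),
    se = apply(z, 2L, sd) * corr / sqrt(nrow(m)),
    n_subjects = nrow(m)
  )
}

#' Condition-wise saccade probabilities with corrected error bars
#'
#' Summarizes the trial table into cells defined by a within-subject
#' factor (and optionally a between-subject factor): the pooled trial
#' proportion of pretarget saccades per cell, the within-subject-corrected
#' SE (computed on per-subject cell means, within each between-subject
#' group), and the cell sizes.
#'
#' @param trials Trial table with `saccade_present`.
#' @param within Name of the within-subject grouping column.
#' @param between Optional name of a between-subject grouping column.
#' @param morey Passed to [within_subject_se()].
#' @return A tibble with the grouping columns, `p_saccade`, `se`,
#'   `n_subjects`, `n_trials`.
#' @export
summarize_saccades <- function(trials, within, between = NULL, morey = TRUE) {
  d <- analysis_subset(trials, need_sfd = FALSE)
  d <- filter(d, !is.na(.data[[within]]))
  grp_b <- if (is.null(between)) "all" else as.character(d[[between]])
  d$..between <- grp_b
  out <- purrr::map(unique(d$..between), function(g) {
    dg <- filter(d, .data$..between == g)
    cells <- dg %>%
      group_by(.data[[within]]) %>%
      summarise(p_saccade = mean(.data$saccade_present),
                n_trials = dplyr::n(), .groups = "drop")
    subj <- dg %>%
      group_by(.data$subject, .data[[within]]) %>%
      summarise(p = mean(.data$saccade_present), .groups = "drop") %>%
      tidyr::pivot_wider(names_from = dplyr::all_of(within),
                         values_from = "p")
    mat <- as.matrix(subj[, -1, drop = FALSE])
    ses <- within_subject_se(mat, morey = morey)
    cells$se <- ses$se[match(as.character(cells[[within]]), ses$condition)]
    cells$n_subjects <- ses$n_subjects[1L]
    if (!is.null(between)) cells[[between]] <- g
    cells
  }) %>% bind_rows()
  cols <- c(between, within, "p_saccade", "se", "n_subjects", "n_trials")
  out[, cols]
}

#' Least-squares overlay fit for summary plots
#'
#' Fits a descriptive curve to group-mean points for figure overlays: a
#' second-degree polynomial (`"poly2"`) or a straight line (`"linear"`).
#' This is plotting machinery only; it is not the inferential model.
#'
#' @param x,y Numeric vectors of cell locations and cell means.
#' @param kind `"poly2"` or `"linear"`.
#' @return Named coefficient vector (`intercept`, `b1`, and `b2` for
#'   `"poly2"`).
#' @export
overlay_fit <- function(x, y, kind = c("poly2", "linear")) {
  kind <- match.arg(kind)
  need <- if (kind == "poly2") 3L else 2L
  if (length(x) < need) abort(sprintf("Need >= %d points for %s.", need, kind))
  f <- if (kind == "poly2") y ~ x + I(x^2) else y ~ x
  fit <- lm(f, data = tibble(x = x, y = y))
  if (any(is.na(coef(fit)))) abort("Rank-deficient overlay fit.")
  setNames(coef(fit), c("intercept", "b1", if (kind == "poly2") "b2"))
}

#' Plot saccade probability against the foreperiod difference
#'
#' Cell means with within-subject-corrected error bars and a
#' second-polynomial overlay, split by foreperiod distribution when
#' present.
#'
#' @param trials Trial table (exp1 design).
#' @return A ggplot object.
#' @export
plot_sfd_profile <- function(trials) {
  between <- if (dplyr::n_distinct(trials$distribution, na.rm = TRUE) > 1L)
    "distribution" else NULL
  s <- summarize_saccades(trials, within = "fp_difference_ms",
                          between = between)
  aes_col <- if (is.null(between)) NULL else ggplot2::aes(colour = .data$distribution)
  p <- ggplot2::ggplot(s, ggplot2::aes(x = .data$fp_difference_ms,
                                       y = .data$p_saccade)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$p_saccade - .data$se,
                                        ymax = .data$p_saccade + .data$se),
                           width = 80) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(formula = y ~ x + I(x^2), method = "lm",
                         se = FALSE, linewidth = 0.6) +
    ggplot2::labs(x = "Foreperiod difference FP(n) - FP(n-1) [ms]",
                  y = "P(saccade in [-300, 0) ms)") +
    ggplot2::theme_minimal()
  if (!is.null(between)) p <- p + ggplot2::aes(colour = .data$distribution)
  p
}

#' Plot saccade probability by condition and foreperiod
#'
#' Cell means with within-subject-corrected error bars and linear
#' overlays, for the fixed/random foreperiod design.
#'
#' @param trials Screened trial table (exp2 design).
#' @return A ggplot object.
#' @export
plot_condition_profile <- function(trials) {
  s <- trials %>%
    mutate(cell = paste(.data$condition, .data$foreperiod_ms)) %>%
    summarize_saccades(within = "cell") %>%
    tidyr::separate_wider_delim("cell", " ",
                                names = c("condition", "foreperiod_ms")) %>%
    mutate(foreperiod_ms = as.numeric(.data$foreperiod_ms))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$foreperiod_ms,
                                  y = .data$p_saccade,
                                  colour = .data$condition)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$p_saccade - .data$se,
                                        ymax = .data$p_saccade + .data$se),
                           width = 80) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(formula = y ~ x, method = "lm", se = FALSE,
                         linewidth = 0.6) +
    ggplot2::labs(x = "Foreperiod [ms]", y = "P(saccade in [-300, 0) ms)",
                  colour = "Condition") +
    ggplot2::theme_minimal()
}

#' Run the full analysis pipeline
#'
#' End-to-end driver: simulate a design (or load sample/event tables),
#' low-pass filter and segment the gaze data, detect blinks and binocular
#' saccades, build the trial table, fit the experiment's mixed model, and
#' summarize. Fully deterministic given `seed`.
#'
#' @param design An [design_spec()]; `NULL` when `samples`/`events` are
#'   supplied.
#' @param samples,events Pre-existing gaze samples and trial-event tables
#'   (used when `design` is `NULL`).
#' @param model [planted_model()] for exp1 designs.
#' @param exp2_effects Named list of [plant_condition_saccades()]
#'   arguments for exp2 designs.
#' @param kin [kinematics_spec()].
#' @param detection [detection_params()].
#' @param cutoff Low-pass cutoff (Hz).
#' @param seed Master seed; all stage seeds derive from it.
#' @param fit Fit the inferential model (set `FALSE` to stop at the trial
#'   table).
#' @return A list of class `"oseq_pipeline"`: `trials`, `saccades`,
#'   `blinks`, `main_sequence`, `model` (an `oseq_exp_fit` or `NULL`),
#'   `summary`, `truth` (when simulated) and `params`.
#' @export
run_pipeline <- function(design = NULL, samples = NULL, events = NULL,
                         model = planted_model(), exp2_effects = list(),
                         kin = kinematics_spec(),
                         detection = detection_params(), cutoff = 60,
                         seed = 1, fit = TRUE) {
  truth <- NULL
  if (is.null(design)) {
    if (is.null(samples) || is.null(events)) {
      abort("Provide either `design` or both `samples` and `events`.")
    }
    experiment <- events$experiment[1L] %||% "exp1"
  } else {
    events <- sample_trial_sequence(design, seed = child_seed(seed, 1L))
    events <- if (design$experiment == "exp1") {
      plant_window_saccades(events, model, seed = child_seed(seed, 2L))
    } else {
      do.call(plant_condition_saccades,
              c(list(trials = events, seed = child_seed(seed, 2L)),
                exp2_effects))
    }
    gaze <- synthesize_gaze(events, kin, seed = child_seed(seed, 3L))
    samples <- gaze$samples
    truth <- gaze$truth
    experiment <- design$experiment
  }
  segments <- segment_gaze(samples, events) %>%
    lowpass_filter(cutoff = cutoff)
  blinks <- detect_blinks(segments)
  saccades <- detect_saccades(segments, blinks, detection)
  trials <- build_trial_table(events, saccades, blinks)
  ms <- main_sequence_check(saccades, trials)
  model_fit <- NULL
  if (fit) {
    model_fit <- if (experiment == "exp1") fit_experiment1(trials)
                 else fit_experiment2(trials)
  }
  summary <- if (experiment == "exp1") {
    summarize_saccades(trials, within = "fp_difference_ms",
                       between = if (dplyr::n_distinct(trials$distribution) > 1L)
                         "distribution" else NULL)
  } else {
    screened <- screen_prev_equal(filter(trials, !.data$excluded))
    screened %>%
      mutate(cell = paste(.data$condition, .data$foreperiod_ms)) %>%
      summarize_saccades(within = "cell")
  }
  structure(list(
    trials = trials, saccades = saccades, blinks = blinks,
    main_sequence = ms, model = model_fit, summary = summary,
    truth = truth,
    params = list(seed = seed, cutoff = cutoff, detection = detection,
                  kin = kin, experiment = experiment)
  ), class = "oseq_pipeline")
}

#' @export
print.oseq_pipeline <- function(x, ...) {
  cat("<oseq_pipeline> ", x$params$experiment, ": ",
      nrow(x$trials), " trials, ", nrow(x$saccades), " saccades, ",
      nrow(x$blinks), " blinks\n", sep = "")
  if (!is.null(x$model)) print(x$model)
  invisible(x)
}
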