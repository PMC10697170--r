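#' Describe a foreperiod experiment design
#'
#' Builds the design descriptor consumed by [sample_trial_sequence()]. Two
#' paradigms are supported. `"exp1"` is a speeded-detection task in which a
#' central cue is followed, after a variable foreperiod, by a lateral target;
#' the five foreperiods are drawn from either a uniform distribution (20%
#' each) or an inverse-U-shaped distribution with sampling weights 1:2:3:2:1.
#' `"exp2"` is a discrimination task with foreperiods 1000-3000 ms in 500-ms
#' steps, administered in *fixed* blocks (one foreperiod throughout the
#' block) and *random* blocks (foreperiod varies trial to trial, uniformly).
#'
#' Defaults reproduce the study-scale designs: for `"exp1"`, 20 subjects per
#' distribution group with 10 blocks of 160 trials (uniform) or 18 blocks of
#' 144 trials (inverse-U); for `"exp2"`, 40 subjects with five fixed blocks
#' (one per foreperiod) plus five random blocks of 100 trials each. Sessions
#' hold up to `blocks_per_session` blocks (8 by default, giving the original
#' 2- and 3-session splits).
#'
#' @param experiment `"exp1"` or `"exp2"`.
#' @param distribution Foreperiod distribution for `"exp1"`: `"uniform"` or
#'   `"inverse_u"`. Ignored for `"exp2"`.
#' @param foreperiod_set Ordered vector of foreperiods (ms). Defaults to
#'   `c(500, 900, 1300, 1700, 2100)` for `"exp1"` and
#'   `seq(1000, 3000, 500)` for `"exp2"`.
#' @param n_subjects Number of subjects.
#' @param n_trials_per_block Trials per block.
#' @param blocks Number of blocks per subject (`"exp1"`). For `"exp2"` the
#'   block count is `n_fixed_blocks + n_random_blocks`.
#' @param n_fixed_blocks,n_random_blocks Block counts per condition
#'   (`"exp2"` only). Fixed blocks cycle through `foreperiod_set`.
#' @param blocks_per_session Maximum blocks per session; the first trial of
#'   each session has no usable previous foreperiod.
#' @param iti_ms Inter-trial interval (ms) between target offset epoch and
#'   the next trial's pre-cue epoch; only affects absolute timestamps.
#'
#' @return A list with class `"oseq_design"`.
#' @examples
#' design_spec("exp1", distribution = "inverse_u", n_subjects = 2,
#'             blocks = 2, n_trials_per_block = 18)
#' @export
design_spec <- function(experiment = c("exp1", "exp2"),
                        distribution = c("uniform", "inverse_u"),
                        foreperiod_set = NULL,
                        n_subjects = NULL,
                        n_trials_per_block = NULL,
                        blocks = NULL,
                        n_fixed_blocks = 5L,
                        n_random_blocks = 5L,
                        blocks_per_session = 8L,
                        iti_ms = 1500) {
  experiment <- match.arg(experiment)
  distribution <- match.arg(distribution)
  if (is.null(foreperiod_set)) {
    foreperiod_set <- if (experiment == "exp1") c(500, 900, 1300, 1700, 2100)
                      else seq(1000, 3000, by = 500)
  }
  if (length(foreperiod_set) == 0L) abort("`foreperiod_set` must be non-empty.")
  if (any(!is.finite(foreperiod_set)) || any(foreperiod_set <= 0)) {
    abort("`foreperiod_set` must contain positive finite durations (ms).")
  }
  foreperiod_set <- sort(unique(as.numeric(foreperiod_set)))

  if (experiment == "exp1") {
    if (is.null(n_subjects)) n_subjects <- 20L
    if (is.null(blocks)) blocks <- if (distribution == "uniform") 10L else 18L
    if (is.null(n_trials_per_block)) {
      n_trials_per_block <- if (distribution == "uniform") 160L else 144L
    }
    weights <- if (distribution == "uniform") {
      rep(1, length(foreperiod_set))
    } else {
      if (length(foreperiod_set) != 5L) {
        abort("inverse_u weighting (1:2:3:2:1) requires 5 foreperiods.")
      }
      c(1, 2, 3, 2, 1)
    }
  } else {
    if (is.null(n_subjects)) n_subjects <- 40L
    blocks <- as.integer(n_fixed_blocks + n_random_blocks)
    if (is.null(n_trials_per_block)) n_trials_per_block <- 100L
    weights <- rep(1, length(foreperiod_set))
  }

  structure(list(
    experiment = experiment,
    distribution = if (experiment == "exp1") distribution else NA_character_,
    foreperiod_set = foreperiod_set,
    weights = weights,
    n_subjects = as.integer(n_subjects),
    n_trials_per_block = as.integer(n_trials_per_block),
    blocks = as.integer(blocks),
    n_fixed_blocks = if (experiment == "exp2") as.integer(n_fixed_blocks) else NA_integer_,
    n_random_blocks = if (experiment == "exp2") as.integer(n_random_blocks) else NA_integer_,
    blocks_per_session = as.integer(blocks_per_session),
    iti_ms = as.numeric(iti_ms)
  ), class = "oseq_design")
}

#' @export
print.oseq_design <- function(x, ...) {
  cat("<oseq_design> ", x$experiment,
      if (!is.na(x$distribution)) paste0(" (", x$distribution, ")"), "\n",
      "  foreperiods (ms): ", paste(x$foreperiod_set, collapse = ", "), "\n",
      "  subjects: ", x$n_subjects,
      ", blocks: ", x$blocks,
      " x ", x$n_trials_per_block, " trials\n", sep = "")
  invisible(x)
}

# Draw foreperiods for one block. When the block length is an exact multiple
# of the weight total, the block is a shuffled exact-ratio allocation (e.g.
# 1:2:3:2:1 over 144 trials); otherwise trials are drawn i.i.d. with the
# design weights.
draw_block_foreperiods <- function(fps, weights, n) {
  wsum <- sum(weights)
  if (n %% wsum == 0L && all(weights == round(weights))) {
    pool <- rep(fps, times = weights * (n %/% wsum))
    sample(pool)
  } else {
    sample(fps, n, replace = TRUE, prob = weights / wsum)
  }
}

#' Sample a trial-event table from a design
#'
#' Generates one row per trial with design factors, the sampled foreperiod,
#' and absolute cue/target onset times. For `"exp1"` designs, uniform blocks
#' give each foreperiod equal probability and inverse-U blocks use 1:2:3:2:1
#' weights; an attention cue (valid/invalid/neutral) is generated but carries
#' no effect downstream. For `"exp2"`, fixed blocks repeat a single
#' foreperiod (cycling through the set across fixed blocks) and random
#' blocks draw uniformly on every trial; block order is shuffled per subject.
#' The first trial of each session is flagged: it has no previous foreperiod.
#'
#' @param design An [design_spec()] object.
#' @param seed Integer seed; identical seeds give bit-identical tables.
#' @return A tibble with columns `subject`, `session`, `block`, `trial`,
#'   `trial_id`, `experiment`, `distribution`, `condition`, `cue`,
#'   `foreperiod_ms`, `cue_onset_ms`, `target_onset_ms`, `first_of_session`.
#'   Times are absolute milliseconds within subject.
#' @examples
#' d <- design_spec("exp1", "uniform", n_subjects = 1, blocks = 1,
#'                  n_trials_per_block = 20)
#' sample_trial_sequence(d, seed = 1)
#' @export
sample_trial_sequence <- function(design, seed = NULL) {
  if (!inherits(design, "oseq_design")) abort("`design` must be an oseq_design.")
  with_rng(seed, {
    subj_tabs <- purrr::map(seq_len(design$n_subjects), function(s) {
      sample_subject_trials(design, s)
    })
    out <- bind_rows(subj_tabs)
    out$trial_id <- seq_len(nrow(out))
    out
  })
}

sample_subject_trials <- function(design, s) {
  nb <- design$blocks
  nt <- design$n_trials_per_block
  if (design$experiment == "exp2") {
    fixed_fp <- rep_len(design$foreperiod_set, design$n_fixed_blocks)
    block_cond <- c(rep("fixed", design$n_fixed_blocks),
                    rep("random", design$n_random_blocks))
    ord <- sample(nb)
    block_cond <- block_cond[ord]
    block_fp <- c(fixed_fp, rep(NA_real_, design$n_random_blocks))[ord]
  } else {
    block_cond <- rep(NA_character_, nb)
    block_fp <- rep(NA_real_, nb)
  }
  session <- ((seq_len(nb) - 1L) %/% design$blocks_per_session) + 1L

  blocks <- purrr::map(seq_len(nb), function(b) {
    fp <- if (design$experiment == "exp2" && block_cond[b] == "fixed") {
      rep(block_fp[b], nt)
    } else {
      draw_block_foreperiods(design$foreperiod_set, design$weights, nt)
    }
    cue <- if (design$experiment == "exp1") {
      sample(c("valid", "invalid", "neutral"), nt, replace = TRUE,
             prob = c(0.5625, 0.1875, 0.25))
    } else {
      rep(NA_character_, nt)
    }
    tibble(
      block = b, session = session[b], trial = seq_len(nt),
      condition = block_cond[b], foreperiod_ms = fp, cue = cue
    )
  })
  tab <- bind_rows(blocks)

  # Absolute timeline: 1000 ms fixation verification before each cue, the
  # foreperiod, then a 500 ms post-target epoch and the ITI.
  pre_cue <- 1000
  post_target <- 500
  dur <- pre_cue + tab$foreperiod_ms + post_target + design$iti_ms
  start <- cumsum(c(0, head(dur, -1L)))
  tab %>%
    mutate(
      subject = sprintf("s%02d", s),
      experiment = design$experiment,
      distribution = design$distribution,
      cue_onset_ms = start + pre_cue,
      target_onset_ms = .data$cue_onset_ms + .data$foreperiod_ms,
      first_of_session = .data$trial == 1L &
        .data$block %in% tapply(.data$block, .data$session, min)[as.character(.data$session)]
    ) %>%
    select("subject", "session", "block", "trial", "experiment",
           "distribution", "condition", "cue", "foreperiod_ms",
           "cue_onset_ms", "target_onset_ms", "first_of_session")
}
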