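#' Fit a binomial-logit (mixed) model
#'
#' Fits a logistic regression of per-trial saccade presence, with optional
#' subject-level random effects estimated by maximum likelihood via the
#' Laplace approximation (lme4). With `random = "none"` the model reduces
#' exactly to ordinary logistic regression (`stats::glm`).
#'
#' Convergence and singularity diagnostics are recorded rather than
#' raised: `converged` is `FALSE` when the optimizer signals failure, and
#' `singular` is `TRUE` when any random-effect variance is at the boundary
#' (variance below `1e-4` on the logit scale or a correlation within
#' `1e-3` of +/-1). Quasi-complete separation is flagged when any fixed
#' coefficient exceeds 15 in magnitude.
#'
#' @param data Trial-level data with the binary response.
#' @param fixed Fixed-effects formula, e.g.
#'   `saccade_present ~ sfd + I(sfd^2) * distribution`.
#' @param random Random-effects specification: a string such as
#'   `"(1 + sfd | subject)"`, or `"none"` for plain logistic regression.
#' @param ... Passed to `lme4::glmer()` / `stats::glm()`.
#' @return An object of class `"oseq_fit"`: a list with `model`,
#'   `coefficients`, `vcov`, `loglik`, `n_params`, `n_obs`, `bic`,
#'   `converged`, `singular`, `separation`, `random`, `varcomp`.
#' @export
fit_glmm <- function(data, fixed, random = "(1 | subject)", ...) {
  resp <- all.vars(fixed)[1L]
  if (!resp %in% names(data)) abort(sprintf("Response `%s` not found.", resp))
  y <- data[[resp]]
  if (!all(as.numeric(y) %in% c(0, 1), na.rm = TRUE)) {
    abort("Response must be binary (0/1 or logical).")
  }
  msgs <- character(0)
  if (is.null(random) || identical(random, "none")) {
    model <- glm(fixed, family = binomial(), data = data, ...)
    converged <- isTRUE(model$converged)
    singular <- FALSE
    varcomp <- tibble(grp = character(), term = character(), var = numeric())
  } else {
    full_formula <- as.formula(
      paste(deparse(fixed, width.cutoff = 500L), "+", random),
      env = environment(fixed) %||% parent.frame()
    )
    model <- withCallingHandlers(
      lme4::glmer(full_formula, family = binomial(), data = data, ...),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    opt_ok <- model@optinfo$conv$opt == 0 &&
      length(model@optinfo$conv$lme4$messages %||% character(0)) == 0L
    converged <- opt_ok && !any(grepl("converge", msgs, ignore.case = TRUE))
    vc <- lme4::VarCorr(model)
    singular <- is_singular_vc(vc)
    varcomp <- varcorr_tibble(vc)
  }
  ll <- logLik(model)
  beta <- if (inherits(model, "merMod")) lme4::fixef(model) else coef(model)
  structure(list(
    model = model,
    formula = fixed,
    random = if (is.null(random)) "none" else random,
    coefficients = beta,
    vcov = as.matrix(vcov(model)),
    loglik = as.numeric(ll),
    n_params = attr(ll, "df"),
    n_obs = stats::nobs(model),
    bic = BIC(model),
    converged = converged,
    singular = singular,
    separation = any(abs(beta) > 15, na.rm = TRUE),
    varcomp = varcomp,
    messages = msgs
  ), class = "oseq_fit")
}

# Boundary check on a VarCorr object: variance < 1e-4 or |corr| > 0.999.
is_singular_vc <- function(vc, var_tol = 1e-4, cor_tol = 0.999) {
  for (g in vc) {
    if (any(diag(g) < var_tol)) return(TRUE)
    cr <- attr(g, "correlation")
    if (!is.null(cr) && nrow(cr) > 1L) {
      off <- cr[lower.tri(cr)]
      if (any(abs(off) > cor_tol)) return(TRUE)
    }
  }
  FALSE
}

varcorr_tibble <- function(vc) {
  bind_rows(purrr::imap(as.list(vc), function(g, nm) {
    tibble(grp = nm, term = rownames(g), var = diag(g))
  }))
}

#' @export
print.oseq_fit <- function(x, ...) {
  cat("<oseq_fit> binomial-logit, random: ", x$random, "\n", sep = "")
  cat("  logLik ", format(x$loglik), ", BIC ", format(x$bic),
      ", n = ", x$n_obs, "\n", sep = "")
  if (!x$converged) cat("  ! did not converge\n")
  if (x$singular) cat("  ! singular random-effect estimate\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @rdname fit_glmm
#' @param x An `oseq_fit`.
#' @exportS3Method generics::tidy
tidy.oseq_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  est <- x$coefficients
  tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(est / se),
    p.value = 2 * pnorm(-abs(unname(est / se)))
  )
}

#' @rdname fit_glmm
#' @exportS3Method generics::glance
glance.oseq_fit <- function(x, ...) {
  tibble(
    logLik = x$loglik, BIC = x$bic, n_params = x$n_params, nobs = x$n_obs,
    converged = x$converged, singular = x$singular, random = x$random
  )
}

# ---------------------------------------------------------------------------

# Random-effects structure string for a set of slope terms by `group`.
ranef_string <- function(slopes, group = "subject") {
  if (!length(slopes)) sprintf("(1 | %s)", group)
  else sprintf("(1 + %s | %s)", paste(slopes, collapse = " + "), group)
}

#' Select the parsimonious random-effects structure
#'
#' Walks the random-effects ladder: a by-subject random intercept first,
#' then random slopes for the within-subject main terms (with their
#' correlations), then interaction slopes. At each rung the model is
#' refitted; a rung that fails to converge or is singular is trimmed by
#' removing the random slope with the least estimated variance and
#' retried. The returned structure is the richest one that converged with
#' no singular estimate. An intercept-only failure is a hard error.
#'
#' @param data Trial-level data.
#' @param fixed Fixed-effects formula.
#' @param slope_terms Character vector of within-subject main-effect terms
#'   eligible for random slopes (e.g. `c("sfd", "I(sfd^2)")`).
#' @param interaction_terms Additional interaction terms tried on the last
#'   rung.
#' @param group Grouping factor (default `"subject"`).
#' @param ... Passed to [fit_glmm()].
#' @return A list: `fit` (the selected `oseq_fit`), `random` (structure
#'   string), and `log`, a tibble auditing every attempted structure.
#' @export
select_random_structure <- function(data, fixed, slope_terms,
                                    interaction_terms = character(0),
                                    group = "subject", ...) {
  log <- list()
  try_fit <- function(slopes) {
    rs <- ranef_string(slopes, group)
    fit <- fit_glmm(data, fixed, random = rs, ...)
    ok <- fit$converged && !fit$singular
    log[[length(log) + 1L]] <<- tibble(
      structure = rs, converged = fit$converged, singular = fit$singular,
      accepted = ok
    )
    list(fit = fit, ok = ok, slopes = slopes)
  }

  base <- try_fit(character(0))
  if (!base$ok) abort("Even the random-intercept-only model failed to fit.")
  best <- base

  stages <- list(slope_terms, c(slope_terms, interaction_terms))
  stages <- unique(stages[lengths(stages) > 0L])
  for (slopes in stages) {
    cur <- slopes
    while (length(cur)) {
      res <- try_fit(cur)
      if (res$ok) {
        if (res$fit$n_params > best$fit$n_params) best <- res
        break
      }
      # trim the slope with the least estimated variance
      vtab <- res$fit$varcomp
      vslopes <- vtab[vtab$term %in% cur, , drop = FALSE]
      drop_term <- if (nrow(vslopes)) vslopes$term[which.min(vslopes$var)] else
        cur[length(cur)]
      cur <- setdiff(cur, drop_term)
    }
  }
  list(fit = best$fit, random = best$fit$random, log = bind_rows(log))
}

# ---------------------------------------------------------------------------

# Variables making up a model term label ("a:b" -> c("a", "b")).
label_vars <- function(label) strsplit(label, ":", fixed = TRUE)[[1L]]

# Drop `labels` from the RHS of `formula`, keeping the response.
drop_labels <- function(formula, labels) {
  tt <- terms(formula)
  keep <- setdiff(attr(tt, "term.labels"), labels)
  resp <- deparse(formula[[2L]])
  if (!length(keep)) keep <- "1"
  as.formula(paste(resp, "~", paste(keep, collapse = " + ")),
             env = environment(formula))
}

#' Type-II likelihood-ratio test of a fixed term
#'
#' Compares nested maximum-likelihood fits following the Type-II
#' convention: interactions containing the tested term are removed from
#' *both* models, the reduced model additionally drops the term itself,
#' and all other terms of equal or lower order are retained. For an
#' interaction the comparison is full vs. no-interaction. The random
#' structure is held fixed across the pair. Several labels can be tested
#' jointly (e.g. linear + quadratic components, df = 2).
#'
#' @param data Trial-level data.
#' @param fixed Full fixed-effects formula.
#' @param term Character vector of term labels tested jointly.
#' @param random Random-effects string as in [fit_glmm()].
#' @param ... Passed to [fit_glmm()].
#' @return A list: `chisq`, `df`, `p`, plus both `oseq_fit`s
#'   (`fit_full`, `fit_reduced`).
#' @export
lr_test_type2 <- function(data, fixed, term, random = "(1 | subject)", ...) {
  labels <- attr(terms(fixed), "term.labels")
  if (!all(term %in% labels)) {
    abort(sprintf("term(s) not in model: %s",
                  paste(setdiff(term, labels), collapse = ", ")))
  }
  tested_vars <- lapply(term, label_vars)
  containing <- labels[vapply(labels, function(l) {
    lv <- label_vars(l)
    !l %in% term && any(vapply(tested_vars, function(tv)
      all(tv %in% lv) && length(lv) > length(tv), logical(1)))
  }, logical(1))]
  full_f <- drop_labels(fixed, containing)
  red_f <- drop_labels(fixed, c(containing, term))
  fit_full <- fit_glmm(data, full_f, random = random, ...)
  fit_red <- fit_glmm(data, red_f, random = random, ...)
  chisq <- max(0, 2 * (fit_full$loglik - fit_red$loglik))
  df <- fit_full$n_params - fit_red$n_params
  if (df < 0) abort("Models are not nested (negative df).")
  p <- if (df == 0) 1 else pchisq(chisq, df, lower.tail = FALSE)
  list(chisq = chisq, df = df, p = p,
       fit_full = fit_full, fit_reduced = fit_red)
}

#' BIC-approximated Bayes factor in favor of the null
#'
#' `BF01 = exp((BIC_full - BIC_reduced) / 2)`: the evidence for the
#' reduced (null) model relative to the full model, from the BIC
#' approximation to the Bayes factor. `BF01 > 1` supports the null.
#'
#' @param fit_full,fit_reduced `oseq_fit` objects fitted to the same data.
#' @return Numeric scalar.
#' @export
bf01_bic <- function(fit_full, fit_reduced) {
  if (fit_full$n_obs != fit_reduced$n_obs) {
    abort("Fits must be on identical data (different n_obs).")
  }
  exp((fit_full$bic - fit_reduced$bic) / 2)
}

# Wald contrasts of linear combinations L %*% beta with BH-FDR over the
# family. L: matrix with one row per contrast.
wald_contrast_table <- function(fit, L, labels, conf_level = 0.95) {
  beta <- fit$coefficients
  est <- as.numeric(L %*% beta)
  se <- sqrt(diag(L %*% fit$vcov %*% t(L)))
  z <- est / se
  p <- 2 * pnorm(-abs(z))
  q <- qnorm(1 - (1 - conf_level) / 2)
  tibble(
    label = labels, estimate = est,
    ci_low = est - q * se, ci_high = est + q * se,
    z_ratio = z, p_raw = p, p_fdr = fdr_adjust(p)
  )
}
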