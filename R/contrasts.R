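#' Build a factor contrast matrix
#'
#' Three codings: `"sum"` (deviation coding; each of the first k-1 levels
#' +1 on its own column, the reference/last level -1, so coefficients
#' compare levels to the grand mean), `"difference"` (successive/backward
#' difference coding; coefficient j estimates level j+1 minus level j), and
#' `"treatment"` (dummy coding against the first level).
#'
#' @param levels Character vector of factor levels (>= 2), in order.
#' @param coding `"sum"`, `"difference"` or `"treatment"`.
#' @return A `length(levels) x (length(levels) - 1)` contrast matrix with
#'   levels as row names.
#' @examples
#' build_contrasts(c("fixed", "random"), "sum")
#' build_contrasts(as.character(1:5), "difference")
#' @export
build_contrasts <- function(levels, coding = c("sum", "difference", "treatment")) {
  coding <- match.arg(coding)
  k <- length(levels)
  if (k < 2L) abort("Need at least 2 levels.")
  m <- switch(coding,
    sum = contr.sum(k),
    difference = MASS::contr.sdif(k),
    treatment = contr.treatment(k)
  )
  rownames(m) <- levels
  m
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity;
#' the input order is preserved.
#'
#' @param p Raw p-values in \[0, 1\].
#' @return Adjusted p-values, same order as `p`.
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}
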