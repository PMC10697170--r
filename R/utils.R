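# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. With seed = NULL the global stream is
# used untouched. Guarantees the determinism contract: same seed, same draws.
with_rng <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a child seed from a parent seed and a stream index, staying within
# 32-bit integer range.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 1009L + as.integer(k) * 9973L) %% 2147483629L
}

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(miss, collapse = ", ")))
  }
  invisible(df)
}

# Maximal runs of TRUE in a logical vector (NA treated as FALSE).
# Returns a two-column matrix of start/end indices.
true_runs <- function(x) {
  x <- !is.na(x) & x
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

# Merge overlapping or touching [start, end] intervals (rows of a matrix),
# assuming numeric bounds. Returns matrix sorted by start.
merge_intervals <- function(m) {
  if (is.null(m) || nrow(m) == 0L) return(m)
  m <- m[order(m[, 1L]), , drop = FALSE]
  out <- m[1L, , drop = FALSE]
  if (nrow(m) > 1L) for (i in 2L:nrow(m)) {
    j <- nrow(out)
    if (m[i, 1L] <= out[j, 2L]) {
      out[j, 2L] <- max(out[j, 2L], m[i, 2L])
    } else {
      out <- rbind(out, m[i, , drop = FALSE])
    }
  }
  out
}
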