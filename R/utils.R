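# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Population standard deviation (divide by n, not n - 1).
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

# Column-wise z-score with the population-sd convention; constant columns
# become all-zero instead of NaN.
zscore_cols <- function(m) {
  out <- m
  for (j in seq_len(ncol(m))) {
    mu <- mean(m[, j])
    s <- pop_sd(m[, j])
    out[, j] <- if (s == 0) 0 else (m[, j] - mu) / s
  }
  out
}

as_dense <- function(m) {
  if (inherits(m, "Matrix")) as.matrix(m) else m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

check_no_duplicates <- function(ids, what) {
  if (anyDuplicated(ids)) {
    stopf("duplicated %s: %s", what,
          paste(unique(ids[duplicated(ids)])[seq_len(min(5, sum(duplicated(ids))))],
                collapse = ", "))
  }
  invisible(ids)
}

# Numerically stable log(1 + exp(x)).
softplus <- function(x) {
  out <- x
  lo <- x < 30
  out[lo] <- log1p(exp(x[lo]))
  out
}
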