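# internal helpers shared across modules

# Set the RNG deterministically when a seed is supplied; NULL leaves the
# current RNG stream untouched.
local_seed <- function(seed) {
  if (is.null(seed)) return(invisible(NULL))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite integer")
  }
  set.seed(as.integer(seed))
  invisible(NULL)
}

# One draw from a multivariate hypergeometric distribution: sample `k` items
# without replacement from categories with sizes `counts`, by the sequential
# conditional method (each category in turn is hypergeometric given the rest).
mvhyper_draw <- function(counts, k) {
  total <- sum(counts)
  if (k > total) stop("cannot draw more items than are present")
  out <- integer(length(counts))
  rem <- total
  for (i in seq_along(counts)) {
    if (k == 0L) break
    ci <- counts[i]
    rem <- rem - ci
    x <- stats::rhyper(1L, ci, rem, k)
    out[i] <- x
    k <- k - x
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
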