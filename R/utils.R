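#' @keywords internal
"_PACKAGE"

# Deterministic apportionment of n among fractions p (largest remainder):
# counts sum to n exactly and equal round(p*n) up to +/-1.
largest_remainder <- function(p, n) {
  stopifnot(all(p >= 0), abs(sum(p) - 1) < 1e-6, n >= 0)
  raw <- p * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    rem <- raw - counts
    # ties broken toward earlier generations (stable order)
    idx <- order(rem, decreasing = TRUE)[seq_len(short)]
    counts[idx] <- counts[idx] + 1
  }
  as.integer(counts)
}

# Run expr with the RNG seeded at `seed`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_if_not_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " must be finite", call. = FALSE)
  invisible(x)
}
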