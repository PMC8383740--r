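# Independent oracles -- deliberately naive implementations used only to
# generate expected values, never sharing code with the package internals.

# Percent undivided via explicit precursor bookkeeping: given per-generation
# precursor counts n_g, the statistic is trivially 100*n_1/sum(n_g).  The
# measured frequencies are reconstructed the way a cytometer would see them
# (each generation-g precursor contributes 2^(g-1) cells).
oracle_phi1_from_precursors <- function(n_g) 100 * n_g[1] / sum(n_g)

oracle_events_from_precursors <- function(n_g, f = 2) {
  n_g * f^(seq_along(n_g) - 1)
}

# Literal running-sum enumeration over every position of the ranked list.
oracle_es <- function(scores, gene_set, p = 1) {
  genes <- names(scores)
  scores <- unname(scores)
  hit <- genes %in% gene_set
  nr <- sum(abs(scores[hit])^p)
  n_miss <- sum(!hit)
  run <- 0
  best <- 0
  profile <- numeric(length(genes))
  for (i in seq_along(genes)) {
    if (hit[i]) run <- run + abs(scores[i])^p / nr
    else run <- run - 1 / n_miss
    profile[i] <- run
    if (abs(run) > abs(best)) best <- run
  }
  list(es = best, profile = profile)
}

# Holm-Sidak adjusted p by definition: the smallest alpha at which the
# step-down Sidak procedure rejects that hypothesis.  Found by bisection,
# independent of the closed form.
oracle_holm_sidak <- function(p, iters = 60) {
  m <- length(p)
  rejects_at <- function(alpha) {
    ord <- order(p)
    rejected <- logical(m)
    for (j in seq_len(m)) {
      thr <- 1 - (1 - alpha)^(1 / (m - j + 1))
      if (p[ord[j]] <= thr) rejected[ord[j]] <- TRUE else break
    }
    rejected
  }
  vapply(seq_len(m), function(i) {
    lo <- 0; hi <- 1
    if (!rejects_at(1)[i]) return(1)
    for (it in seq_len(iters)) {
      mid <- (lo + hi) / 2
      if (rejects_at(mid)[i]) hi <- mid else lo <- mid
    }
    hi
  }, numeric(1))
}

# Upper-tail hypergeometric by direct PMF summation with choose().
oracle_hyper_tail <- function(k, set_size, universe, n_draw) {
  kk <- k:min(set_size, n_draw)
  sum(choose(set_size, kk) * choose(universe - set_size, n_draw - kk)) /
    choose(universe, n_draw)
}

random_simplex <- function(n, alpha = 1) {
  x <- stats::rgamma(n, alpha)
  x / sum(x)
}

# Recovery fixture: profiles emulating the study's cultures, where controls
# leave ~20% undivided and inhibited cultures up to ~60%.
random_recovery_profile <- function(G) {
  p1 <- stats::runif(1, 0.1, 0.5)
  rest <- random_simplex(G - 1, alpha = 2) * (1 - p1)
  division_profile(c(p1, rest))
}
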