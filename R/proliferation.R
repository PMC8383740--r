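# Precursor (cohort) arithmetic: a measured generation-g peak of frequency
# X_g represents X_g / f^(g-1) original input cells, because each precursor
# that reached generation g contributed f^(g-1) descendants (f = dilution
# factor, 2 for a halving dye).  All statistics below are ratios of such
# precursor counts and are therefore invariant to the scale of X.

freqs_of <- function(X) {
  if (inherits(X, "generation_frequencies")) return(X$X)
  X <- as.numeric(X)
  if (length(X) < 1 || any(X < 0) || any(!is.finite(X)))
    stop("X must be finite and non-negative", call. = FALSE)
  if (sum(X) <= 0) stop("X must not be all zero", call. = FALSE)
  X
}

precursor_counts <- function(X, dilution_factor = 2) {
  X / dilution_factor^(seq_along(X) - 1)
}

#' Percent undivided (precursor-normalized)
#'
#' The fraction of original input cells that never divided, as a percent:
#' `Phi_1 = 100 * X_1 / (X_1 + sum_{i=1..D} X_{i+1} / f^i)` where `D` is the
#' number of observed divisions (peaks minus one) and `f` the per-division
#' dilution factor.  Dividing each peak frequency by `f^(g-1)` converts
#' measured cell frequencies into precursor counts, so the statistic equals
#' `100 * n_1 / sum(n_g)` exactly on cohorts with known per-generation
#' precursor counts `n_g`.
#'
#' @param X a [generation_frequencies()] or numeric frequency vector
#'   (percent or counts; the ratio is scale-invariant).
#' @param dilution_factor per-division dilution (default 2).
#' @return percent undivided in `[0, 100]`.
#' @examples
#' percent_undivided(c(50, 50))          # 66.67: 50 undivided + 25 divided precursors
#' percent_undivided(c(40, 30, 20, 10))  # 65.31
#' @export
percent_undivided <- function(X, dilution_factor = 2) {
  n <- precursor_counts(freqs_of(X), dilution_factor)
  100 * n[1] / sum(n)
}

#' Percent-undivided series over generation truncations
#'
#' `Phi_k` applies the percent-undivided statistic to the sub-vector
#' `X[k..D+1]` re-indexed so generation `k` is the first peak (the analysis
#' "excluding generations 1..k-1 before gating").  `Phi_{D+1} = 100` by
#' construction.
#'
#' @inheritParams percent_undivided
#' @return numeric vector `Phi_1..Phi_{D+1}`.
#' @export
phi_series <- function(X, dilution_factor = 2) {
  X <- freqs_of(X)
  vapply(seq_along(X), function(k)
    percent_undivided(X[k:length(X)], dilution_factor), numeric(1))
}

#' Percent division series
#'
#' `theta_i = 100 - Phi_i`, the percent of the (truncated) input cohort that
#' divided at least once.  Plotting `theta_i` against `i` gives the
#' mathematical form of a FACS proliferation curve.
#'
#' @inheritParams percent_undivided
#' @return numeric vector `theta_1..theta_{D+1}` (`theta_{D+1} = 0`).
#' @export
theta_series <- function(X, dilution_factor = 2) {
  100 - phi_series(X, dilution_factor)
}

#' Standard cohort proliferation indices
#'
#' With precursor counts `n_g = X_g / f^(g-1)`:
#' division index = mean divisions per input cell
#' (`sum((g-1) n_g) / sum(n_g)`); proliferation index = mean divisions per
#' *dividing* input cell (`sum((g-1) n_g) / sum_{g>=2}(n_g)`, 0 if nothing
#' divided); expansion index = fold expansion of the culture
#' (`sum(X_g) / sum(n_g)`).
#'
#' @inheritParams percent_undivided
#' @return named list: division_index, proliferation_index, expansion_index.
#' @export
proliferation_indices <- function(X, dilution_factor = 2) {
  X <- freqs_of(X)
  n <- precursor_counts(X, dilution_factor)
  g0 <- seq_along(X) - 1
  divs <- sum(g0 * n)
  dividing <- sum(n[-1])
  list(division_index = divs / sum(n),
       proliferation_index = if (dividing > 0) divs / dividing else 0,
       expansion_index = sum(X) / sum(n))
}

#' Per-sample proliferation summary
#'
#' Bundles `Phi`, `theta`, `D`, the cohort indices and generation bins for
#' one sample.
#'
#' @inheritParams percent_undivided
#' @param sample_id identifier carried into comparison reports.
#' @return object of class `proliferation_summary`.
#' @export
proliferation_summary <- function(X, dilution_factor = 2,
                                  sample_id = "sample") {
  Xv <- freqs_of(X)
  Xv <- 100 * Xv / sum(Xv)
  phi <- phi_series(Xv, dilution_factor)
  structure(list(sample_id = sample_id, X = Xv, D = length(Xv) - 1L,
                 Phi = phi, Theta = 100 - phi,
                 indices = proliferation_indices(Xv, dilution_factor),
                 bins = bin_generations(Xv)),
            class = "proliferation_summary")
}

#' @export
print.proliferation_summary <- function(x, ...) {
  cat(sprintf("<proliferation_summary> '%s': D = %d, Phi_1 = %.2f%%\n",
              x$sample_id, x$D, x$Phi[1]))
  cat(sprintf("  DI %.3f | PI %.3f | EI %.3f | Gen1 %.1f%% Gen6+ %.1f%%\n",
              x$indices$division_index, x$indices$proliferation_index,
              x$indices$expansion_index, x$bins["Gen1"], x$bins["Gen6plus"]))
  invisible(x)
}

#' Holm-Sidak step-down adjusted p-values
#'
#' Sorts raw p-values ascending and applies
#' `adj_(k) = max_{j<=k} 1 - (1 - p_(j))^(m - j + 1)`, clipped to 1, then
#' returns the adjustment in the original order.  Equals the raw p when
#' `m = 1` and is never below it.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values, same order as `p`.
#' @examples
#' holm_sidak(c(0.01, 0.04))  # 0.0199, 0.04
#' @export
holm_sidak <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- pmin(cummax(1 - (1 - ps)^(m - seq_len(m) + 1)), 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Compare proliferation between two conditions
#'
#' The headline effect is the percent change in mean percent-undivided:
#' `100 * (mean Phi_1 treated - mean Phi_1 control) / mean Phi_1 control`.
#' Each shared generation's `theta_i` is compared with an unpaired
#' two-tailed t-test (Welch by default; pooled variance for single-well
#' assays) and the per-generation p-values are Holm-Sidak adjusted.  The
#' per-sample division numbers `D` are compared with a Mann-Whitney U test
#' (midranks on ties).  Degenerate (zero-variance) generations are flagged
#' with `NA` p-values rather than fabricated ones.
#'
#' @param treated,control lists of [proliferation_summary()] objects.
#' @param method `"welch"` or `"pooled"` for the per-generation t-tests.
#' @return object of class `comparison_result`: effect size, per-generation
#'   table (theta means, raw and adjusted p), median divisions and the
#'   Mann-Whitney p.
#' @export
compare_conditions <- function(treated, control,
                               method = c("welch", "pooled")) {
  method <- match.arg(method)
  as_list <- function(x) if (inherits(x, "proliferation_summary")) list(x)
                         else x
  treated <- as_list(treated); control <- as_list(control)
  stopifnot(length(treated) >= 1, length(control) >= 1)
  for (s in c(treated, control))
    stopifnot(inherits(s, "proliferation_summary"))

  phi1_t <- vapply(treated, function(s) s$Phi[1], numeric(1))
  phi1_c <- vapply(control, function(s) s$Phi[1], numeric(1))
  effect <- 100 * (mean(phi1_t) - mean(phi1_c)) / mean(phi1_c)

  n_gen <- min(vapply(c(treated, control), function(s) length(s$Theta),
                      integer(1)))
  theta_mat <- function(ss) t(vapply(ss, function(s) s$Theta[seq_len(n_gen)],
                                     numeric(n_gen)))
  tt <- theta_mat(treated); tc <- theta_mat(control)
  can_test <- length(treated) >= 2 && length(control) >= 2
  raw_p <- rep(NA_real_, n_gen)
  flags <- character(n_gen)
  for (i in seq_len(n_gen)) {
    a <- tt[, i]; b <- tc[, i]
    if (!can_test) { flags[i] <- "too_few_samples"; next }
    raw_p[i] <- tryCatch(
      stats::t.test(a, b, var.equal = (method == "pooled"))$p.value,
      error = function(e) {
        flags[i] <<- "degenerate_variance"
        NA_real_
      })
  }
  degenerate <- is.nan(raw_p)
  flags[degenerate] <- "degenerate_variance"
  raw_p[degenerate] <- NA_real_
  adj_p <- rep(NA_real_, n_gen)
  tested <- !is.na(raw_p)
  if (any(tested)) adj_p[tested] <- holm_sidak(raw_p[tested])

  d_t <- vapply(treated, function(s) s$D, integer(1))
  d_c <- vapply(control, function(s) s$D, integer(1))
  mw_p <- if (can_test)
    suppressWarnings(stats::wilcox.test(d_t, d_c)$p.value) else NA_real_

  structure(list(
    effect_percent_increase_undivided = effect,
    mean_phi1 = c(treated = mean(phi1_t), control = mean(phi1_c)),
    per_generation = data.frame(
      generation = seq_len(n_gen),
      theta_treated = colMeans(tt), theta_control = colMeans(tc),
      theta_diff = colMeans(tt) - colMeans(tc),
      p_raw = raw_p, p_adj = adj_p, flag = flags,
      stringsAsFactors = FALSE),
    median_divisions = c(treated = stats::median(d_t),
                         control = stats::median(d_c)),
    mann_whitney_p = mw_p,
    method = method), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %+.1f%% change in percent undivided ",
              x$effect_percent_increase_undivided))
  cat(sprintf("(Phi_1 %.1f vs %.1f)\n", x$mean_phi1["treated"],
              x$mean_phi1["control"]))
  cat(sprintf("median divisions %.1f vs %.1f (Mann-Whitney p = %s)\n",
              x$median_divisions["treated"], x$median_divisions["control"],
              format.pval(x$mann_whitney_p, digits = 3)))
  print(x$per_generation, digits = 3)
  invisible(x)
}

#' One-way ANOVA across multiple conditions
#'
#' Convenience wrapper for aggregate multi-condition comparisons of a
#' per-sample statistic (default `Phi_1`).
#'
#' @param summaries_by_condition named list of lists of
#'   [proliferation_summary()].
#' @param statistic function extracting a scalar per summary.
#' @return list with the ANOVA table and the extracted values.
#' @export
anova_conditions <- function(summaries_by_condition,
                             statistic = function(s) s$Phi[1]) {
  stopifnot(is.list(summaries_by_condition),
            length(summaries_by_condition) >= 2)
  vals <- lapply(summaries_by_condition, function(ss)
    vapply(ss, statistic, numeric(1)))
  df <- data.frame(value = unlist(vals),
                   condition = rep(names(vals), lengths(vals)))
  fit <- stats::aov(value ~ condition, data = df)
  list(table = summary(fit)[[1]], data = df,
       p = summary(fit)[[1]][["Pr(>F)"]][1])
}
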