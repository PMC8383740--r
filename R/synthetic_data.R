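#' Division profile of a labelled precursor cohort
#'
#' The latent state of a dye-dilution experiment: the fraction of input
#' ("precursor") cells that end the culture in each generation.  Generation
#' 1 is undivided; generation `g` corresponds to `g - 1` completed divisions.
#'
#' @param fractions non-negative numeric vector summing to 1 (within 1e-9),
#'   indexed by generation.
#' @return object of class `division_profile`.
#' @examples
#' division_profile(c(0.5, 0.3, 0.2))
#' @export
division_profile <- function(fractions) {
  stop_if_not_finite(fractions, "precursor fractions")
  if (length(fractions) < 1 || any(fractions < 0))
    stop("fractions must be non-negative and non-empty", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must sum to 1 (got ", format(sum(fractions)), ")",
         call. = FALSE)
  structure(as.numeric(fractions) / sum(fractions),
            class = "division_profile")
}

#' Dye labelling / measurement model
#'
#' Parameters of the fluorescence model in log10 units.  The label halves
#' with each division (daughters inherit ~50% of the labelled protein), so a
#' generation-`g` cell sits `(g-1) * log10(dilution_factor)` below the
#' initial peak; measurement noise combines the initial labelling spread, a
#' per-division inheritance jitter (accumulating as `sqrt(g-1)`), and the
#' instrument CV, all in quadrature.  Autofluorescence acts as a hard floor
#' (censoring), reproducing the pile-up of high-generation peaks.
#'
#' @param log10_initial_mean mean log10 fluorescence of the undivided peak.
#' @param log10_initial_sd sd of the initial label (log10 units).
#' @param dilution_factor per-division intensity dilution (default exactly 2).
#' @param inheritance_sd per-division log10 jitter.
#' @param autofluorescence_floor hard lower bound (log10 units).
#' @param instrument_cv_log10 instrument measurement sd (log10 units).
#' @return object of class `labeling_model`.
#' @export
labeling_model <- function(log10_initial_mean = 4.5,
                           log10_initial_sd = 0.08,
                           dilution_factor = 2,
                           inheritance_sd = 0,
                           autofluorescence_floor = 1.5,
                           instrument_cv_log10 = 0.04) {
  stop_if_not_finite(c(log10_initial_mean, log10_initial_sd, dilution_factor,
                       inheritance_sd, instrument_cv_log10),
                     "labeling model parameters")
  if (dilution_factor <= 1) stop("dilution_factor must be > 1", call. = FALSE)
  if (log10_initial_sd < 0 || inheritance_sd < 0 || instrument_cv_log10 < 0)
    stop("sd/cv parameters must be >= 0", call. = FALSE)
  structure(list(log10_initial_mean = log10_initial_mean,
                 log10_initial_sd = log10_initial_sd,
                 dilution_factor = dilution_factor,
                 inheritance_sd = inheritance_sd,
                 autofluorescence_floor = autofluorescence_floor,
                 instrument_cv_log10 = instrument_cv_log10),
            class = "labeling_model")
}

#' Simulate a dye-dilution cohort
#'
#' Assigns each of `n_precursors` input cells a final generation from
#' `profile`, expands a generation-`g` precursor into
#' `dilution_factor^(g-1)` descendant events (synchronous, complete
#' division; no death), and draws one measured log10 fluorescence per event.
#' Every event carries its true generation, so deconvolution and the
#' downstream proliferation statistics can be validated against ground
#' truth.
#'
#' With `assignment = "quota"` (the default) per-generation precursor counts
#' are `round(p_g * n)` with largest-remainder correction, which makes the
#' realized event count exactly `sum_g n_g * 2^(g-1)` and the
#' percent-undivided statistic algebraically exact; `"multinomial"` draws
#' counts stochastically.
#'
#' @param profile a [division_profile()].
#' @param n_precursors number of input cells (>= 1).
#' @param labeling a [labeling_model()].
#' @param seed integer seed.
#' @param assignment `"quota"` or `"multinomial"`.
#' @param max_events refuse to simulate more than this many events.
#' @return an [event_table()] with channel `CellTrace` (log10-transformed)
#'   plus `event_id` and `true_generation` columns.
#' @examples
#' lm <- labeling_model(log10_initial_sd = 0.06, instrument_cv_log10 = 0)
#' et <- simulate_cohort(division_profile(c(0.5, 0.3, 0.2)), 1000, lm, seed = 1)
#' table(et$true_generation)
#' @export
simulate_cohort <- function(profile, n_precursors, labeling = labeling_model(),
                            seed = NULL,
                            assignment = c("quota", "multinomial"),
                            max_events = 5e6) {
  assignment <- match.arg(assignment)
  stopifnot(inherits(profile, "division_profile"),
            inherits(labeling, "labeling_model"))
  if (n_precursors < 1) stop("n_precursors must be >= 1", call. = FALSE)
  G <- length(profile)
  df <- labeling$dilution_factor
  per_prec <- round(df^(seq_len(G) - 1))
  expected <- n_precursors * sum(unclass(profile) * per_prec)
  if (expected > max_events)
    stop("expected event count ", format(expected, big.mark = ","),
         " exceeds max_events = ", format(max_events, big.mark = ","),
         call. = FALSE)

  with_seed(seed, {
    n_g <- if (assignment == "quota")
      largest_remainder(unclass(profile), n_precursors)
    else
      as.integer(stats::rmultinom(1, n_precursors, unclass(profile)))
    ev_per_gen <- n_g * per_prec
    gen <- rep.int(seq_len(G), ev_per_gen)
    n_ev <- length(gen)
    sd_g <- sqrt(labeling$log10_initial_sd^2 +
                 (seq_len(G) - 1) * labeling$inheritance_sd^2 +
                 labeling$instrument_cv_log10^2)
    mu_g <- labeling$log10_initial_mean - (seq_len(G) - 1) * log10(df)
    fluor <- mu_g[gen] + stats::rnorm(n_ev, 0, 1) * sd_g[gen]
    fluor <- pmax(fluor, labeling$autofluorescence_floor)
    ord <- sample.int(n_ev)
    event_table(data.frame(event_id = seq_len(n_ev),
                           CellTrace = fluor[ord],
                           true_generation = gen[ord]),
                sample_id = "simulated_cohort",
                transforms = c(CellTrace = "log10"))
  })
}

#' Simulate a concentration series of treated cohorts
#'
#' Models a dose-dependent block of division as a multiplier on the
#' undivided precursor fraction: at concentration `c` the undivided fraction
#' becomes `min(1, p_1 * effect(c))` and the dividing generations are
#' rescaled to keep the profile summing to 1.  `effect(0)` must equal 1 (the
#' null dose leaves the base profile untouched); a non-monotone effect map
#' is accepted but flagged with a warning.
#'
#' @param base_profile a [division_profile()].
#' @param concentrations non-negative numeric vector.
#' @param effect function mapping concentration to an undivided-fraction
#'   multiplier (>= 0).
#' @param n_precursors precursors per concentration.
#' @param labeling a [labeling_model()].
#' @param seed integer seed (each concentration gets a derived sub-seed).
#' @param ... passed to [simulate_cohort()].
#' @return named list of [event_table()]s, one per concentration.
#' @export
simulate_dose_series <- function(base_profile, concentrations, effect,
                                 n_precursors, labeling = labeling_model(),
                                 seed = NULL, ...) {
  stopifnot(inherits(base_profile, "division_profile"),
            is.function(effect), all(concentrations >= 0))
  if (abs(effect(0) - 1) > 1e-9)
    stop("effect(0) must equal 1", call. = FALSE)
  mult <- vapply(concentrations, effect, numeric(1))
  stop_if_not_finite(mult, "effect multipliers")
  if (is.unsorted(mult[order(concentrations)]) &&
      is.unsorted(rev(mult[order(concentrations)])))
    warning("effect map is not monotone in concentration", call. = FALSE)
  p <- unclass(base_profile)
  out <- vector("list", length(concentrations))
  for (k in seq_along(concentrations)) {
    p1 <- min(1, p[1] * mult[k])
    prof <- if (length(p) == 1) 1 else {
      rest <- p[-1]
      scale <- if (sum(rest) > 0) (1 - p1) / sum(rest) else 0
      c(p1, rest * scale)
    }
    sub_seed <- if (is.null(seed)) NULL else (seed + k) %% .Machine$integer.max
    et <- simulate_cohort(division_profile(prof / sum(prof)), n_precursors,
                          labeling, seed = sub_seed, ...)
    attr(et, "sample_id") <- sprintf("conc_%g", concentrations[k])
    out[[k]] <- et
  }
  names(out) <- sprintf("conc_%g", concentrations)
  out
}

#' Configuration for the negative-binomial count simulator
#'
#' @param n_genes number of background genes.
#' @param group_sizes integer pair: samples in group 1 and group 2.
#' @param baseline_mean_log_range log10 range from which per-gene baseline
#'   means are drawn uniformly.
#' @param dispersion NB dispersion alpha (> 0); variance = mu + alpha*mu^2.
#' @param de_fraction fraction of background genes carrying the planted fold
#'   change in group 2.
#' @param fold_change planted linear fold change (>= 1; direction is
#'   randomized per gene).
#' @param library_size_factors per-sample library scaling (positive; default
#'   all 1).
#' @param paralog_groups named list mapping a group name to member gene
#'   names; members are appended as extra non-DE genes with independent
#'   baselines so paralog read-grouping rules can be exercised.
#' @param seed integer seed.
#' @return object of class `count_sim_config`.
#' @export
count_sim_config <- function(n_genes = 2000, group_sizes = c(4, 4),
                             baseline_mean_log_range = c(0.5, 3),
                             dispersion = 0.1, de_fraction = 0.1,
                             fold_change = 4,
                             library_size_factors = NULL,
                             paralog_groups = list(), seed = 1) {
  stopifnot(n_genes >= 1, length(group_sizes) == 2, all(group_sizes >= 1),
            length(baseline_mean_log_range) == 2,
            de_fraction >= 0, de_fraction <= 1, fold_change >= 1)
  if (dispersion <= 0) stop("dispersion must be > 0", call. = FALSE)
  n_samp <- sum(group_sizes)
  if (is.null(library_size_factors)) library_size_factors <- rep(1, n_samp)
  if (length(library_size_factors) != n_samp || any(library_size_factors <= 0))
    stop("library_size_factors must be ", n_samp, " positive values",
         call. = FALSE)
  members <- unlist(paralog_groups, use.names = FALSE)
  if (anyDuplicated(members))
    stop("paralog group members must be disjoint", call. = FALSE)
  structure(list(n_genes = as.integer(n_genes),
                 group_sizes = as.integer(group_sizes),
                 baseline_mean_log_range = baseline_mean_log_range,
                 dispersion = dispersion, de_fraction = de_fraction,
                 fold_change = fold_change,
                 library_size_factors = library_size_factors,
                 paralog_groups = paralog_groups, seed = as.integer(seed)),
            class = "count_sim_config")
}

#' Simulate a count matrix with planted differential expression
#'
#' Draws gene-by-sample negative-binomial counts with per-sample library
#' scaling.  Exactly `round(de_fraction * n_genes)` background genes carry
#' the planted fold change in group 2 (direction randomized); paralog group
#' members are appended as additional null genes with independent baselines.
#' The returned object bundles the [count_matrix()] with a truth table for
#' benchmarking differential-expression calls.
#'
#' @param config a [count_sim_config()].
#' @return list with elements `matrix` (a [count_matrix()]) and `truth`
#'   (data.frame: gene, is_de, true_fc).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "count_sim_config"))
  with_seed(config$seed, {
    n_bg <- config$n_genes
    members <- unlist(config$paralog_groups, use.names = FALSE)
    genes <- c(sprintf("gene%04d", seq_len(n_bg)), members)
    n_genes <- length(genes)
    n_samp <- sum(config$group_sizes)
    grp <- rep(c("group1", "group2"), config$group_sizes)

    base <- 10^stats::runif(n_genes, config$baseline_mean_log_range[1],
                            config$baseline_mean_log_range[2])
    n_de <- round(config$de_fraction * n_bg)
    de_idx <- if (n_de > 0) sort(sample.int(n_bg, n_de)) else integer(0)
    fc <- rep(1, n_genes)
    if (n_de > 0) {
      up <- stats::runif(n_de) < 0.5
      fc[de_idx] <- ifelse(up, config$fold_change, 1 / config$fold_change)
    }
    mu <- outer(base, config$library_size_factors)
    mu[, grp == "group2"] <- mu[, grp == "group2"] * fc
    counts <- matrix(stats::rnbinom(n_genes * n_samp, mu = mu,
                                    size = 1 / config$dispersion),
                     nrow = n_genes,
                     dimnames = list(genes, sprintf("%s_s%d", grp,
                                                    seq_len(n_samp))))
    lengths_bp <- round(10^stats::runif(n_genes, log10(300), log10(10000)))
    cm <- count_matrix(counts, gene_lengths = lengths_bp,
                       sample_groups = stats::setNames(grp, colnames(counts)),
                       paralog_groups = config$paralog_groups)
    truth <- data.frame(gene = genes,
                        is_de = fc != 1,
                        true_fc = fc,
                        stringsAsFactors = FALSE)
    list(matrix = cm, truth = truth)
  })
}
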