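#' Read / write GMT gene-set files
#'
#' GMT is tab-separated: set name, description, then member genes.
#'
#' @param path file path.
#' @param sets named list of character vectors (for writing).
#' @param descriptions optional per-set descriptions.
#' @return `read_gmt` returns a named list of gene vectors;
#'   `write_gmt` returns `path` invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 60),
                            call. = FALSE)
    f[-(1:2)][nzchar(f[-(1:2)])]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  out
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, d, genes)
    paste(c(nm, d, genes), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Signal-to-noise ranking scores
#'
#' `(mean_A - mean_B) / (sd_A' + sd_B')` per gene, with each sd floored at
#' `max(0.2 * |mean|, 0.2)` (the reference GSEA convention, which keeps
#' scores finite for flat genes).  Requires at least two samples per group.
#'
#' @param matrix expression matrix (genes x samples) or [count_matrix()].
#' @param groupA,groupB sample names (or group labels for a
#'   [count_matrix()]).
#' @return named numeric score vector (not yet sorted).
#' @export
signal2noise <- function(matrix, groupA, groupB) {
  if (inherits(matrix, "count_matrix")) {
    grp <- matrix$sample_groups
    if (all(groupA %in% grp)) groupA <- names(grp)[grp %in% groupA]
    if (all(groupB %in% grp)) groupB <- names(grp)[grp %in% groupB]
    matrix <- matrix$counts
  }
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("signal2noise needs >= 2 samples per group; ",
         "use a log2 fold-change ranking instead", call. = FALSE)
  A <- matrix[, groupA, drop = FALSE]
  B <- matrix[, groupB, drop = FALSE]
  floor_sd <- function(s, m) pmax(s, pmax(0.2 * abs(m), 0.2))
  ma <- rowMeans(A); mb <- rowMeans(B)
  sa <- floor_sd(apply(A, 1, stats::sd), ma)
  sb <- floor_sd(apply(B, 1, stats::sd), mb)
  (ma - mb) / (sa + sb)
}

#' Build a ranked list
#'
#' @param scores named numeric scores (e.g. from [signal2noise()]).
#' @return named numeric vector sorted descending (class `ranked_list`).
#' @export
ranked_list <- function(scores) {
  if (is.null(names(scores)) || anyDuplicated(names(scores)))
    stop("scores must be named with unique gene ids", call. = FALSE)
  stop_if_not_finite(scores, "ranking scores")
  structure(sort(scores, decreasing = TRUE), class = "ranked_list")
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list: at a gene-set hit the running sum rises by
#' `|score|^p / sum_set(|score|^p)`, at a miss it falls by `1 / (N - n)`.
#' The enrichment score is the signed maximum deviation from zero.  With
#' `p = 0` this is the classic Kolmogorov-Smirnov statistic; `p = 1`
#' (default) weights hits by their scores.
#'
#' @param ranked a [ranked_list()] (or a named, descending numeric vector).
#' @param gene_set character vector of member genes.
#' @param p hit weighting exponent (0 or 1).
#' @return list: `es`, `running` (profile of length N), `arg_es` (position
#'   of the extremum), `hits` (hit positions), `leading_edge` (genes).
#' @export
enrichment_score <- function(ranked, gene_set, p = 1) {
  scores <- unclass(ranked)
  genes <- names(scores)
  N <- length(scores)
  hit <- genes %in% gene_set
  n <- sum(hit)
  if (n == 0) stop("gene set has no genes in the ranked list", call. = FALSE)
  w <- abs(scores)^p
  inc <- numeric(N)
  inc[hit] <- w[hit] / sum(w[hit])
  if (N > n) inc[!hit] <- -1 / (N - n)
  running <- cumsum(inc)
  arg <- which.max(abs(running))
  es <- running[arg]
  hp <- which(hit)
  le <- if (es >= 0) genes[hp[hp <= arg]] else genes[hp[hp >= arg]]
  list(es = es, running = running, arg_es = arg, hits = hp,
       leading_edge = le)
}

# ES extrema from hit positions only: O(n_set) per evaluation.  Between
# consecutive hits the running sum decays linearly, so candidate extrema are
# the values right after each hit and right before each hit.
es_from_hits <- function(idx, inc_hit, N) {
  n <- length(idx)
  miss <- if (N > n) 1 / (N - n) else 0
  cum_hit <- cumsum(inc_hit)
  after <- cum_hit - (idx - seq_len(n)) * miss
  before <- c(0, cum_hit[-n]) - (idx - 1 - (seq_len(n) - 1)) * miss
  cand <- c(after, before)
  cand[which.max(abs(cand))]
}

#' Gene-set enrichment with permutation FDR
#'
#' Scores every gene set on the ranked list, builds a null distribution
#' from `n_perm` random gene sets of matching size (`mode = "gene_set"`,
#' the default), and reports the normalized enrichment score
#' (`NES = ES / mean |null ES| of the same sign`), a nominal permutation p,
#' and an FDR q computed by the standard signed null-pool ratio: for a set
#' with `NES >= 0`, q is the fraction of pooled null NES at least as large
#' divided by the fraction of observed NES at least as large (clipped to
#' `[0, 1]`).  Sets with fewer than `min_size` or more than `max_size`
#' members in the list are skipped with a message.
#'
#' @param ranked a [ranked_list()].
#' @param gene_sets named list of gene vectors (e.g. from [read_gmt()]).
#' @param n_perm number of permutations (>= 100).
#' @param mode only `"gene_set"` permutation is implemented; phenotype
#'   permutation requires the sample-level matrix and is out of scope here.
#' @param seed integer seed (results are deterministic given it).
#' @param p hit weighting exponent.
#' @param min_size,max_size gene-set size filters (reference defaults
#'   15-500).
#' @param q_cutoff enrichment threshold on FDR q (default 0.25).
#' @return data.frame: set, size, es, nes, pval, qval, enriched,
#'   leading_edge (comma-separated).
#' @export
permutation_fdr <- function(ranked, gene_sets, n_perm = 1000,
                            mode = "gene_set", seed = NULL, p = 1,
                            min_size = 15, max_size = 500,
                            q_cutoff = 0.25) {
  stopifnot(identical(mode, "gene_set"))
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  scores <- unclass(ranked)
  genes <- names(scores)
  N <- length(scores)
  w <- abs(scores)^p

  sizes <- vapply(gene_sets, function(s) sum(genes %in% s), integer(1))
  keep <- sizes >= min_size & sizes <= max_size
  if (any(!keep))
    message("permutation_fdr: skipping ", sum(!keep),
            " set(s) outside size ", min_size, "-", max_size)
  gene_sets <- gene_sets[keep]
  sizes <- sizes[keep]
  if (!length(gene_sets)) stop("no gene set passes the size filter",
                               call. = FALSE)

  obs <- lapply(gene_sets, function(s) enrichment_score(ranked, s, p))
  es_obs <- vapply(obs, `[[`, numeric(1), "es")

  with_seed(seed, {
    uniq_sizes <- sort(unique(sizes))
    null_es <- list()  # per unique size: n_perm null ES
    for (k in uniq_sizes) {
      null_es[[as.character(k)]] <- vapply(seq_len(n_perm), function(i) {
        idx <- sort(sample.int(N, k))
        es_from_hits(idx, w[idx] / sum(w[idx]), N)
      }, numeric(1))
    }
    nes_obs <- numeric(length(es_obs))
    pval <- numeric(length(es_obs))
    null_nes_pool <- numeric(0)
    null_nes_by_set <- vector("list", length(es_obs))
    warned <- FALSE
    for (j in seq_along(es_obs)) {
      null <- null_es[[as.character(sizes[j])]]
      pos <- null[null >= 0]; neg <- null[null < 0]
      es <- es_obs[j]
      if (es >= 0) {
        if (length(pos)) {
          nes_obs[j] <- es / mean(pos)
          pval[j] <- mean(pos >= es)
        } else {
          nes_obs[j] <- NA_real_; pval[j] <- 1; warned <- TRUE
        }
      } else {
        if (length(neg)) {
          nes_obs[j] <- es / mean(abs(neg))
          pval[j] <- mean(neg <= es)
        } else {
          nes_obs[j] <- NA_real_; pval[j] <- 1; warned <- TRUE
        }
      }
      nn <- null
      nn[null >= 0] <- if (length(pos)) null[null >= 0] / mean(pos) else NA
      nn[null < 0] <- if (length(neg)) null[null < 0] / mean(abs(neg)) else NA
      null_nes_by_set[[j]] <- nn
    }
    if (warned)
      warning("all null ES of one sign for some set; q forced to 1 there",
              call. = FALSE)
    null_nes_pool <- unlist(null_nes_by_set)
    null_nes_pool <- null_nes_pool[is.finite(null_nes_pool)]
    qval <- vapply(seq_along(nes_obs), function(j) {
      nes <- nes_obs[j]
      if (!is.finite(nes)) return(1)
      if (nes >= 0) {
        num_pool <- null_nes_pool[null_nes_pool >= 0]
        num <- if (length(num_pool)) mean(num_pool >= nes) else 1
        den <- mean(nes_obs[is.finite(nes_obs)] >= nes)
      } else {
        num_pool <- null_nes_pool[null_nes_pool < 0]
        num <- if (length(num_pool)) mean(num_pool <= nes) else 1
        den <- mean(nes_obs[is.finite(nes_obs)] <= nes)
      }
      min(1, num / max(den, .Machine$double.eps))
    }, numeric(1))
    data.frame(set = names(gene_sets), size = sizes, es = es_obs,
               nes = nes_obs, pval = pval, qval = qval,
               enriched = qval < q_cutoff,
               leading_edge = vapply(obs, function(o)
                 paste(o$leading_edge, collapse = ","), character(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  })
}

#' Hypergeometric gene-set overlap test
#'
#' Upper-tail hypergeometric (one-sided Fisher) test of the overlap between
#' a gene list (e.g. DEGs) and each gene set, over an explicit universe,
#' with Benjamini-Hochberg adjustment.  Sets are intersected with the
#' universe (with a warning when trimmed); the gene list must already lie
#' within the universe.
#'
#' @param deg_list character vector of genes of interest.
#' @param gene_sets named list of gene vectors.
#' @param universe character vector: all assayable genes.
#' @param q_cutoff significance threshold on the BH q-value (default 0.005).
#' @return data.frame: set, set_size, overlap, pval, qval, significant,
#'   overlap_genes.
#' @export
overlap_test <- function(deg_list, gene_sets, universe, q_cutoff = 0.005) {
  universe <- unique(universe)
  deg_list <- unique(deg_list)
  outside <- setdiff(deg_list, universe)
  if (length(outside))
    stop("gene list contains genes outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
  n_uni <- length(universe)
  n_deg <- length(deg_list)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- unique(gene_sets[[nm]])
    trimmed <- intersect(set, universe)
    if (length(trimmed) < length(set))
      warning("set '", nm, "' trimmed to the universe (",
              length(trimmed), "/", length(set), " genes)", call. = FALSE)
    ov <- intersect(deg_list, trimmed)
    k <- length(ov); m <- length(trimmed)
    # P(overlap >= k) drawing n_deg genes from the universe
    p <- stats::phyper(k - 1, m, n_uni - m, n_deg, lower.tail = FALSE)
    data.frame(set = nm, set_size = m, overlap = k, pval = p,
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$qval <- stats::p.adjust(out$pval, "BH")
  out$significant <- out$qval < q_cutoff
  out[, c("set", "set_size", "overlap", "pval", "qval", "significant",
          "overlap_genes")]
}
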