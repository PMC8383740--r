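#' Gene-by-sample count matrix
#'
#' Integer read counts with per-gene lengths, sample group labels and
#' optional paralog groupings (e.g. `FCGR2 = FCGR2A + FCGR2B + FCGR2C`,
#' whose transcripts are too similar for reads to be assigned uniquely).
#'
#' @param counts non-negative numeric gene x sample matrix with rownames
#'   (genes) and colnames (samples).
#' @param gene_lengths positive lengths in bases, one per gene (kilobases
#'   are derived by division where needed).
#' @param sample_groups named character vector mapping sample to group
#'   label; defaults to a single group.
#' @param paralog_groups named list mapping group name to member gene names.
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, gene_lengths,
                         sample_groups = NULL, paralog_groups = list()) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("gene names must be unique", call. = FALSE)
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and non-negative", call. = FALSE)
  if (length(gene_lengths) != nrow(counts) || any(gene_lengths <= 0))
    stop("gene_lengths must be positive, one per gene", call. = FALSE)
  if (is.null(sample_groups))
    sample_groups <- stats::setNames(rep("all", ncol(counts)),
                                     colnames(counts))
  if (!all(colnames(counts) %in% names(sample_groups)))
    stop("every sample needs a group label", call. = FALSE)
  structure(list(counts = counts,
                 gene_lengths = stats::setNames(as.numeric(gene_lengths),
                                                rownames(counts)),
                 sample_groups = sample_groups[colnames(counts)],
                 paralog_groups = paralog_groups),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d samples; groups: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$sample_groups), collapse = ", ")))
  invisible(x)
}

#' Default Fc-gamma receptor paralog groups
#'
#' FCGR2A/B/C and FCGR3A/B transcripts are nearly indistinguishable at the
#' read level, so reads are pooled per family and counted once.
#' @return named list of member gene vectors.
#' @export
fcgr_paralog_groups <- function() {
  list(FCGR2 = c("FCGR2A", "FCGR2B", "FCGR2C"),
       FCGR3 = c("FCGR3A", "FCGR3B"))
}

#' Collapse paralog gene families into single rows
#'
#' Each group's counts are summed (every read counted once) and its gene
#' lengths are summed, then the member rows are removed.  Missing members
#' are logged, not fatal; overlapping groups are an error.
#'
#' @param matrix a [count_matrix()].
#' @param groups named list of member gene names; default
#'   [fcgr_paralog_groups()] or the matrix's own `paralog_groups` if set.
#' @return a [count_matrix()] with grouped rows.
#' @export
group_paralogs <- function(matrix, groups = NULL) {
  stopifnot(inherits(matrix, "count_matrix"))
  if (is.null(groups))
    groups <- if (length(matrix$paralog_groups)) matrix$paralog_groups
              else fcgr_paralog_groups()
  members <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(members))
    stop("paralog groups overlap: ",
         paste(unique(members[duplicated(members)]), collapse = ", "),
         call. = FALSE)
  counts <- matrix$counts
  lens <- matrix$gene_lengths
  new_rows <- list(); new_lens <- numeric(0)
  drop <- character(0)
  for (nm in names(groups)) {
    present <- intersect(groups[[nm]], rownames(counts))
    missing <- setdiff(groups[[nm]], rownames(counts))
    if (length(missing))
      message("group_paralogs: ", nm, " member(s) absent: ",
              paste(missing, collapse = ", "))
    if (!length(present)) next
    new_rows[[nm]] <- colSums(counts[present, , drop = FALSE])
    new_lens[nm] <- sum(lens[present])
    drop <- c(drop, present)
  }
  keep <- setdiff(rownames(counts), drop)
  out_counts <- rbind(counts[keep, , drop = FALSE],
                      do.call(rbind, new_rows))
  out_lens <- c(lens[keep], new_lens)
  count_matrix(out_counts, out_lens, matrix$sample_groups,
               paralog_groups = list())
}

#' Median-of-ratios size factors
#'
#' The library-size estimator used by DESeq-style normalization: per-gene
#' geometric means form a pseudo-reference, and each sample's factor is the
#' median of its counts' ratios to that reference over genes expressed in
#' every sample (`method = "ratio"`), or over genes with a positive
#' geometric mean (`method = "poscounts"`).
#'
#' @param matrix a [count_matrix()] or plain count matrix.
#' @param method `"ratio"` (classic) or `"poscounts"`.
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(matrix, method = c("ratio", "poscounts")) {
  method <- match.arg(method)
  counts <- if (inherits(matrix, "count_matrix")) matrix$counts else
    as.matrix(matrix)
  if (method == "ratio") {
    use <- rowSums(counts > 0) == ncol(counts)
    if (!any(use))
      stop("no gene has nonzero counts in all samples; ",
           "try method = \"poscounts\"", call. = FALSE)
    geo <- exp(rowMeans(log(counts[use, , drop = FALSE])))
    sf <- apply(counts[use, , drop = FALSE], 2,
                function(col) stats::median(col / geo))
  } else {
    lc <- log(counts)
    lc[!is.finite(lc)] <- NA
    log_geo <- rowMeans(lc, na.rm = TRUE) *
      (rowSums(!is.na(lc)) / ncol(counts))  # poscounts-style shrink
    use <- is.finite(log_geo)
    geo <- exp(log_geo[use])
    sf <- apply(counts[use, , drop = FALSE], 2, function(col) {
      r <- col / geo
      stats::median(r[col > 0])
    })
  }
  sf / exp(mean(log(sf)))  # geometric mean 1
}

#' Normalized reads per kilobase
#'
#' `(count / size factor) / gene length in kb` -- the expression unit used
#' for surveying receptor genes in library-size-normalized bulk data.
#' Grouped paralog rows automatically use the summed group length.
#'
#' @param matrix a [count_matrix()].
#' @param factors size factors from [size_factors()]; computed if omitted.
#' @return numeric matrix of normalized per-kb expression values.
#' @export
normalized_per_kb <- function(matrix, factors = NULL) {
  stopifnot(inherits(matrix, "count_matrix"))
  if (is.null(factors)) factors <- size_factors(matrix)
  norm <- sweep(matrix$counts, 2, factors, "/")
  sweep(norm, 1, matrix$gene_lengths / 1000, "/")
}

#' Transcripts per million
#'
#' Length-normalized within-sample abundance: `rate = count / length`;
#' `TPM = 1e6 * rate / sum(rate)` per sample, so every column sums to 1e6.
#'
#' @param matrix a [count_matrix()], or a plain count matrix with
#'   `gene_lengths` supplied.
#' @param gene_lengths lengths in bases (only for plain matrices).
#' @return TPM matrix.
#' @export
tpm <- function(matrix, gene_lengths = NULL) {
  if (inherits(matrix, "count_matrix")) {
    counts <- matrix$counts
    gene_lengths <- matrix$gene_lengths
  } else {
    counts <- as.matrix(matrix)
    if (is.null(gene_lengths)) stop("gene_lengths required", call. = FALSE)
  }
  rate <- counts / gene_lengths
  totals <- colSums(rate)
  zero <- totals == 0
  if (any(zero)) {
    warning("all-zero column(s): ",
            paste(colnames(counts)[zero], collapse = ", "), call. = FALSE)
    totals[zero] <- 1
  }
  sweep(rate, 2, totals, "/") * 1e6
}

#' Threshold-based expression calls
#'
#' Classifies per-subset mean TPM with inclusive thresholds: `>= 1`
#' expressed; `>= 0.5` very low; `>= 0.25` still included in rankings;
#' otherwise absent.  A gene's `basal` flag records whether any subset
#' averaged `>= 1.2` TPM (the evidence bar for discussing a gene at all).
#'
#' @param tpm_matrix TPM matrix (genes x samples).
#' @param subsets named list mapping subset name to its sample names.
#' @return data.frame with gene, subset, mean_tpm, call, basal.
#' @export
expression_calls <- function(tpm_matrix, subsets) {
  stopifnot(is.matrix(tpm_matrix), is.list(subsets), length(subsets) > 0)
  if (is.null(names(subsets)) || any(names(subsets) == ""))
    stop("subsets must be named", call. = FALSE)
  for (nm in names(subsets)) {
    if (!length(subsets[[nm]]))
      stop("subset '", nm, "' is empty", call. = FALSE)
    missing <- setdiff(subsets[[nm]], colnames(tpm_matrix))
    if (length(missing))
      stop("subset '", nm, "' names unknown sample(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  means <- vapply(subsets, function(ss)
    rowMeans(tpm_matrix[, ss, drop = FALSE]), numeric(nrow(tpm_matrix)))
  means <- matrix(means, nrow = nrow(tpm_matrix),
                  dimnames = list(rownames(tpm_matrix), names(subsets)))
  call_of <- function(m)
    ifelse(m >= 1, "expressed",
           ifelse(m >= 0.5, "very_low",
                  ifelse(m >= 0.25, "below_ranking", "absent")))
  basal <- apply(means, 1, function(m) any(m >= 1.2))
  out <- data.frame(gene = rep(rownames(means), times = ncol(means)),
                    subset = rep(colnames(means), each = nrow(means)),
                    mean_tpm = as.vector(means),
                    call = as.vector(call_of(means)),
                    basal = rep(basal, times = ncol(means)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# NB log-likelihood on (possibly non-integer) normalized counts with
# common mean mu and dispersion a (variance mu + a*mu^2).
nb_loglik <- function(k, mu, a) {
  r <- 1 / a
  sum(lgamma(k + r) - lgamma(r) - lgamma(k + 1) +
      k * log(mu / (mu + r)) + r * log(r / (mu + r)))
}

# Convenience per-gene NB likelihood-ratio test: median-of-ratios
# normalization, pooled within-group method-of-moments dispersion floored at
# the genome-wide median (conservative moderation), then a deviance test of
# group means against the pooled mean (chi-square, 1 df).  Deliberately NOT
# a DESeq2 clone: supplying externally computed statistics to
# deg_classify() is the fidelity path.
nb_lrt_test <- function(matrix, group1, group2, pseudocount = 0.5) {
  counts <- matrix$counts
  grp <- matrix$sample_groups
  a <- names(grp)[grp == group1]
  b <- names(grp)[grp == group2]
  if (length(a) < 2 || length(b) < 2)
    stop("built-in test needs >= 2 samples per group; supply external ",
         "per-gene statistics instead", call. = FALSE)
  sf <- size_factors(matrix)
  norm <- sweep(counts, 2, sf, "/")
  ma <- rowMeans(norm[, a, drop = FALSE])
  mb <- rowMeans(norm[, b, drop = FALSE])
  m0 <- rowMeans(norm)
  va <- apply(norm[, a, drop = FALSE], 1, stats::var)
  vb <- apply(norm[, b, drop = FALSE], 1, stats::var)
  disp <- ((va - ma) / ma^2 + (vb - mb) / mb^2) / 2
  disp[!is.finite(disp)] <- NA
  disp_med <- stats::median(disp[disp > 0], na.rm = TRUE)
  if (!is.finite(disp_med)) disp_med <- 1e-4
  disp <- pmax(disp, disp_med, 1e-8, na.rm = TRUE)
  lr <- vapply(seq_len(nrow(norm)), function(g) {
    k <- norm[g, ]
    al <- disp[g]
    2 * (nb_loglik(k[a], max(ma[g], 1e-8), al) +
         nb_loglik(k[b], max(mb[g], 1e-8), al) -
         nb_loglik(k, max(m0[g], 1e-8), al))
  }, numeric(1))
  p <- stats::pchisq(pmax(lr, 0), df = 1, lower.tail = FALSE)
  data.frame(gene = rownames(counts),
             log2fc = log2((mb + pseudocount) / (ma + pseudocount)),
             pvalue = p,
             padj = stats::p.adjust(p, "BH"),
             stringsAsFactors = FALSE)
}

#' Classify differential-expression calls
#'
#' Applies the two-tier rule: a gene is a DEG if the adjusted p-value is
#' `< 0.05` and the linear fold change is `>= 1.5` in either direction;
#' non-DEGs are trend calls (up/down) if either the adjusted or the nominal
#' p-value is `< 0.10`; everything else is `ns`.
#'
#' @param x either a data.frame with columns `gene`, `log2fc` (or `fc`),
#'   `pvalue`, `padj`, or a [count_matrix()] (the built-in NB
#'   likelihood-ratio test with BH adjustment is then run between `group1`
#'   and `group2`).
#' @param group1,group2 group labels when `x` is a matrix (reference first:
#'   fold changes are group2 / group1).
#' @param padj_cutoff,fc_cutoff,trend_cutoff rule thresholds.
#' @return object of class `deg_table`: the per-gene table plus a `class`
#'   column and class counts in `attr(, "class_counts")`.
#' @export
deg_classify <- function(x, group1 = "group1", group2 = "group2",
                         padj_cutoff = 0.05, fc_cutoff = 1.5,
                         trend_cutoff = 0.10) {
  if (inherits(x, "count_matrix"))
    x <- nb_lrt_test(x, group1, group2)
  stopifnot(is.data.frame(x))
  if (!"log2fc" %in% names(x)) {
    if (!"fc" %in% names(x))
      stop("need a log2fc or fc column", call. = FALSE)
    x$log2fc <- log2(x$fc)
  }
  need <- setdiff(c("gene", "pvalue", "padj"), names(x))
  if (length(need))
    stop("missing column(s): ", paste(need, collapse = ", "), call. = FALSE)
  if (any(x$padj < x$pvalue - 1e-12, na.rm = TRUE))
    warning("some padj < pvalue; check the adjustment", call. = FALSE)
  big_fc <- abs(x$log2fc) >= log2(fc_cutoff)
  is_deg <- !is.na(x$padj) & x$padj < padj_cutoff & big_fc
  trendy <- !is_deg &
    (pmin(x$padj, x$pvalue, na.rm = TRUE) < trend_cutoff) & x$log2fc != 0
  cls <- rep("ns", nrow(x))
  cls[is_deg & x$log2fc > 0] <- "DEG_up"
  cls[is_deg & x$log2fc < 0] <- "DEG_down"
  cls[trendy & x$log2fc > 0] <- "up_trend"
  cls[trendy & x$log2fc < 0] <- "down_trend"
  x$class <- cls
  attr(x, "class_counts") <- table(factor(cls, levels = c(
    "DEG_up", "DEG_down", "up_trend", "down_trend", "ns")))
  class(x) <- c("deg_table", "data.frame")
  x
}

#' Per-cell counts per million for grouped genes
#'
#' For single-cell matrices: `cpm = 1e6 * sum(group member counts) / total
#' counts` per cell.  Cells with zero total counts are dropped (count
#' logged).
#'
#' @param counts gene x cell count matrix with rownames.
#' @param groups named list of member gene vectors (default
#'   [fcgr_paralog_groups()]).
#' @return matrix: one row per group, one column per retained cell.
#' @export
sc_cpm <- function(counts, groups = fcgr_paralog_groups()) {
  counts <- as.matrix(counts)
  totals <- colSums(counts)
  zero <- totals == 0
  if (any(zero)) {
    message("sc_cpm: dropping ", sum(zero), " zero-total cell(s)")
    counts <- counts[, !zero, drop = FALSE]
    totals <- totals[!zero]
  }
  out <- vapply(groups, function(members) {
    present <- intersect(members, rownames(counts))
    if (!length(present)) return(rep(0, ncol(counts)))
    1e6 * colSums(counts[present, , drop = FALSE]) / totals
  }, numeric(ncol(counts)))
  t(matrix(out, ncol = length(groups),
           dimnames = list(colnames(counts), names(groups))))
}
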