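tiny_matrix <- function() {
  counts <- matrix(c(10, 5, 3, 100, 20,
                     20, 10, 6, 200, 40), ncol = 2,
                   dimnames = list(c("FCGR2A", "FCGR2B", "FCGR2C", "ACTB",
                                     "CD3E"), c("s1", "s2")))
  count_matrix(counts, gene_lengths = c(4000, 3000, 3000, 2000, 1000),
               sample_groups = c(s1 = "g1", s2 = "g2"))
}

test_that("paralog grouping sums counts and lengths, removes members", {
  cm <- tiny_matrix()
  g <- group_paralogs(cm, list(FCGR2 = c("FCGR2A", "FCGR2B", "FCGR2C")))
  expect_equal(unname(g$counts["FCGR2", ]), c(18, 36))
  expect_equal(unname(g$gene_lengths["FCGR2"]), 10000)
  expect_false(any(c("FCGR2A", "FCGR2B", "FCGR2C") %in% rownames(g$counts)))
  expect_message(group_paralogs(cm, list(FCGR3 = c("FCGR3A", "FCGR3B"))),
                 "absent")
  expect_error(group_paralogs(cm, list(a = "ACTB", b = c("ACTB", "CD3E"))),
               "overlap")
})

test_that("grouping commutes with TPM and normalized-per-kb", {
  set.seed(51)
  for (rep in 1:5) {
    counts <- matrix(rpois(50 * 4, 60), nrow = 50,
                     dimnames = list(sprintf("g%02d", 1:50),
                                     paste0("s", 1:4)))
    lens <- sample(500:5000, 50)
    cm <- count_matrix(counts, lens)
    groups <- list(GRP1 = c("g01", "g02", "g03"), GRP2 = c("g10", "g11"))
    grouped <- group_paralogs(cm, groups)
    # pre-summed fixture built independently
    pre <- rbind(counts[setdiff(rownames(counts),
                                unlist(groups)), , drop = FALSE],
                 GRP1 = colSums(counts[groups$GRP1, ]),
                 GRP2 = colSums(counts[groups$GRP2, ]))
    pre_lens <- c(lens[match(setdiff(rownames(counts), unlist(groups)),
                             rownames(counts))],
                  sum(lens[1:3]), sum(lens[10:11]))
    cm_pre <- count_matrix(pre, pre_lens)
    t1 <- tpm(grouped)
    t2 <- tpm(cm_pre)
    expect_equal(t1[rownames(t2), ], t2, tolerance = 1e-9)
    n1 <- normalized_per_kb(grouped, rep(1, 4))
    n2 <- normalized_per_kb(cm_pre, rep(1, 4))
    expect_equal(n1[rownames(n2), ], n2, tolerance = 1e-9)
  }
})

test_that("size factors reproduce the median-of-ratios definition", {
  counts <- matrix(rpois(20 * 3, 50) + 1, nrow = 20,
                   dimnames = list(paste0("g", 1:20), c("a", "b", "c")))
  sf <- size_factors(counts)
  # brute force on the same 20-gene fixture
  geo <- exp(rowMeans(log(counts)))
  brute <- apply(counts, 2, function(col) median(col / geo))
  brute <- brute / exp(mean(log(brute)))
  expect_equal(unname(sf), unname(brute), tolerance = 1e-12)
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-12)
  # identical columns -> all 1; doubled column -> ratio 2
  same <- matrix(rep(1:10, 2), ncol = 2,
                 dimnames = list(paste0("g", 1:10), c("a", "b")))
  expect_equal(unname(size_factors(same)), c(1, 1))
  dbl <- same; dbl[, 2] <- dbl[, 2] * 2
  sfd <- size_factors(dbl)
  expect_equal(unname(sfd[2] / sfd[1]), 2, tolerance = 1e-12)
  zero <- matrix(c(0, 5, 3, 0), 2,
                 dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_error(size_factors(zero), "poscounts")
  expect_silent(size_factors(zero, method = "poscounts"))
})

test_that("normalized per-kb expression follows its definition", {
  cm <- count_matrix(matrix(100, 1, 1, dimnames = list("g", "s")),
                     gene_lengths = 2000)
  expect_equal(unname(normalized_per_kb(cm, factors = 1)[1, 1]), 50)
  expect_equal(unname(normalized_per_kb(cm, factors = 2)[1, 1]), 25)
})

test_that("TPM columns sum to one million and match the hand fixture", {
  cm <- count_matrix(matrix(c(10, 90), 2, 1,
                            dimnames = list(c("a", "b"), "s")),
                     gene_lengths = c(1000, 3000))
  expect_equal(unname(tpm(cm)[, 1]), c(250000, 750000))
  # single gene
  one <- count_matrix(matrix(7, 1, 1, dimnames = list("g", "s")), 500)
  expect_equal(unname(tpm(one)[1, 1]), 1e6)
  # equal lengths -> TPM proportional to counts
  eq <- count_matrix(matrix(c(1, 2, 3, 6), 2,
                            dimnames = list(c("a", "b"), c("s1", "s2"))),
                     gene_lengths = c(1000, 1000))
  expect_equal(unname(tpm(eq)[, 1]), c(1, 2) / 3 * 1e6)
  set.seed(52)
  counts <- matrix(rpois(200, 30), 50,
                   dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
  expect_true(all(abs(colSums(tpm(count_matrix(counts,
    sample(300:3000, 50)))) - 1e6) < 1e-3))
  zc <- count_matrix(matrix(c(1, 0), 1, 2,
                            dimnames = list("g", c("a", "b"))), 100)
  expect_warning(tz <- tpm(zc), "all-zero")
  expect_equal(unname(tz[, 2]), 0)
})

test_that("expression calls apply inclusive thresholds and the basal rule", {
  tpm_m <- matrix(c(1.3, 0.6, 0.3, 0.1, 1.0, 1.19,
                    1.3, 0.6, 0.3, 0.1, 1.0, 1.21), ncol = 2,
                  dimnames = list(paste0("g", 1:6), c("s1", "s2")))
  calls <- expression_calls(tpm_m, list(all = c("s1", "s2")))
  expect_equal(calls$call,
               c("expressed", "very_low", "below_ranking", "absent",
                 "expressed", "expressed"))
  expect_equal(calls$basal, c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE))
  # two subsets: basal if ANY subset mean >= 1.2
  two <- expression_calls(tpm_m, list(a = "s1", b = "s2"))
  expect_true(all(two$basal[two$gene == "g6"]))
  expect_error(expression_calls(tpm_m, list(a = character(0))), "empty")
  expect_error(expression_calls(tpm_m, list(a = "nope")), "unknown sample")
})

test_that("DEG classification implements the two-tier rule", {
  df <- data.frame(gene = paste0("g", 1:6),
                   fc = c(1.6, 1 / 1.6, 1.4, 1.2, 1.05, 2.0),
                   pvalue = c(0.001, 0.002, 0.04, 0.05, 0.5, 0.3),
                   padj = c(0.04, 0.04, 0.04, 0.08, 0.9, 0.4))
  out <- deg_classify(df)
  expect_equal(out$class,
               c("DEG_up",      # padj<0.05 & fc>=1.5
                 "DEG_down",    # the other direction
                 "up_trend",    # padj<0.05 but fc<1.5 -> trend tier
                 "up_trend",    # padj<0.10
                 "ns", "ns"))
  cc <- attr(out, "class_counts")
  expect_equal(as.vector(cc[c("DEG_up", "DEG_down", "up_trend")]),
               c(1, 1, 2))
  expect_error(deg_classify(data.frame(gene = "g", pvalue = 1, padj = 1)),
               "log2fc or fc")
})

test_that("built-in test controls FDR and finds planted signal", {
  sim <- simulate_counts(count_sim_config(n_genes = 1000, seed = 61))
  deg <- deg_classify(sim$matrix)
  called <- deg$gene[deg$class %in% c("DEG_up", "DEG_down")]
  truth_de <- sim$truth$gene[sim$truth$is_de]
  fdr <- sum(!called %in% truth_de) / max(1, length(called))
  sens <- sum(called %in% truth_de) / length(truth_de)
  expect_lte(fdr, 0.10)
  expect_gte(sens, 0.6)
  # direction agrees with the planted fold change
  # true-positive up-calls must carry the planted up direction
  up_called <- deg$gene[deg$class == "DEG_up"]
  tp_up <- up_called[up_called %in% truth_de]
  planted_up <- sim$truth$gene[sim$truth$true_fc > 1]
  expect_gt(mean(tp_up %in% planted_up), 0.95)
  # n = 1 per group refuses
  cm1 <- count_matrix(sim$matrix$counts[, c(1, 5)],
                      sim$matrix$gene_lengths,
                      sample_groups = setNames(c("group1", "group2"),
                                     colnames(sim$matrix$counts)[c(1, 5)]))
  expect_error(deg_classify(cm1), ">= 2 samples")
})

test_that("BH adjustment inside the built-in test is sane", {
  sim <- simulate_counts(count_sim_config(n_genes = 300, seed = 62))
  deg <- deg_classify(sim$matrix)
  expect_true(all(deg$padj >= deg$pvalue - 1e-12))
  expect_equal(deg$padj, p.adjust(deg$pvalue, "BH"))
})

test_that("single-cell cpm follows its definition and drops empty cells", {
  counts <- matrix(0, 5, 3,
                   dimnames = list(c("FCGR2A", "FCGR2B", "CD3E", "ACTB",
                                     "FCGR3A"),
                                   c("c1", "c2", "c3")))
  counts["FCGR2A", "c1"] <- 3; counts["FCGR2B", "c1"] <- 2
  counts["CD3E", "c1"] <- 9995
  counts["ACTB", "c2"] <- 50
  # c3 all zero -> dropped
  expect_message(out <- sc_cpm(counts), "zero-total")
  expect_identical(colnames(out), c("c1", "c2"))
  expect_equal(out["FCGR2", "c1"], 500)
  expect_equal(out["FCGR2", "c2"], 0)
  # grouping-order invariance
  out2 <- sc_cpm(counts[sample(rownames(counts)), c(1, 2)],
                 rev(fcgr_paralog_groups()))
  expect_equal(out2["FCGR2", "c1"], 500)
})
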