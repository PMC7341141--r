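test_that("QTL ranking applies mean ranks at ties and the ceil percent rank", {
  qtl <- qtl_region("q", paste0("g", 1:5))
  scores <- stats::setNames(c(0.9, 0.9, 0.5, 0.5, 0.1), paste0("g", 1:5))
  r <- rank_qtl(scores, qtl)
  expect_equal(r$rank, c(1.5, 1.5, 3.5, 3.5, 5))
  expect_equal(r$percent_rank, c(30, 30, 70, 70, 100))
  # a single-gene interval is rank 1, percent rank 100
  one <- rank_qtl(c(g9 = 0.4), qtl_region("q1", "g9"))
  expect_equal(one$rank, 1)
  expect_equal(one$percent_rank, 100)
  expect_error(rank_qtl(scores, qtl_region("q2", c("g1", "zz"))), "zz")
})

test_that("top 20% of a 335-gene interval is exactly 67 genes", {
  ids <- sprintf("g%03d", 1:335)
  set.seed(1)
  scores <- stats::setNames(runif(335), ids)
  r <- rank_qtl(scores, qtl_region("height", ids))
  expect_equal(sum(r$percent_rank <= 20), 67)
  expect_equal(ceiling(0.20 * 335), 67)
  # the best gene of a 144-gene interval prints as the top 1%
  ids2 <- sprintf("h%03d", 1:144)
  r2 <- rank_qtl(stats::setNames(runif(144), ids2),
                 qtl_region("light", ids2))
  expect_equal(min(r2$percent_rank), 1)
})

test_that("sorghum validation table reproduces the published recalls", {
  tab <- sorghum_table()
  expect_equal(nrow(tab), 10)
  expect_equal(names(tab), c("trait", "gene_name", "gene_id",
                             "genes_in_qtl", "percent_rank"))
  rec <- recall_at_cutoffs(tab$percent_rank, c(5, 10, 20))
  expect_equal(unname(rec), c(0.30, 0.30, 0.70))
  expect_equal(unname(recall_at_cutoffs(tab$percent_rank, 100)), 1)
})

test_that("sorghum validation table reproduces the published precisions", {
  tab <- sorghum_table()
  prec <- average_precision_at_cutoffs(tab$genes_in_qtl, tab$percent_rank,
                                       c(5, 10, 20))
  expect_equal(round(unname(prec), 3), c(0.065, 0.041, 0.044))
  # one 10-gene QTL with its causal gene first: 1 / ceiling(2) at top 20%
  expect_equal(unname(average_precision_at_cutoffs(10, 10, 20)), 0.5)
})

test_that("recall is monotone in the cutoff and precision is bounded", {
  tab <- sorghum_table()
  cuts <- c(5, 10, 20, 50, 100)
  expect_true(all(diff(recall_at_cutoffs(tab$percent_rank, cuts)) >= 0))
  # per-QTL precision is 0 exactly when the causal gene is not recalled
  prec20 <- ifelse(tab$percent_rank <= 20,
                   1 / ceiling(0.2 * tab$genes_in_qtl), 0)
  expect_true(all(prec20[tab$percent_rank > 20] == 0))
  expect_true(all(prec20 <= 1))
})

test_that("theoretical background is the selected fraction", {
  expect_equal(theoretical_background(c(5, 10, 20)), c(0.05, 0.10, 0.20))
  expect_equal(theoretical_background(100), 1)
  expect_error(theoretical_background(0), "cutoff")
  expect_error(theoretical_background(101), "cutoff")
})

test_that("Fisher model comparison matches hypergeometric enumeration", {
  expect_equal(fisher_compare(c(7, 3), c(7, 3)), 1.0)
  expect_equal(fisher_compare(c(10, 0), c(0, 10)),
               enumerate_fisher_p(10, 0, 0, 10))
  expect_equal(fisher_compare(c(7, 3), c(6, 4)),
               enumerate_fisher_p(7, 3, 6, 4))
  # sorghum vs Arabidopsis-sized comparison is not significant
  expect_gt(fisher_compare(c(7, 3), c(6, 4)), 0.05)
  for (tab in list(c(2, 6, 5, 1), c(4, 4, 1, 7), c(3, 0, 2, 3))) {
    expect_equal(fisher_compare(tab[1:2], tab[3:4]),
                 enumerate_fisher_p(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-7)
  }
  expect_warning(p <- fisher_compare(c(0, 5), c(0, 7)), "degenerate")
  expect_equal(p, 1)
})

test_that("Mann-Whitney enrichment matches exhaustive enumeration", {
  got <- enrichment_test(c(5, 6, 7), c(1, 2, 3))
  want <- enumerate_mw(c(5, 6, 7), c(1, 2, 3))
  expect_equal(got$statistic, want$statistic)
  expect_equal(got$p.value, want$p.value)
  set.seed(12)
  for (i in 1:4) {
    x <- sample(1:10, 4, replace = TRUE)   # ties likely
    y <- sample(1:10, 4, replace = TRUE)
    got <- enrichment_test(x, y)
    want <- enumerate_mw(x, y)
    expect_equal(got$statistic, want$statistic)
    expect_equal(got$p.value, want$p.value)
  }
  expect_equal(enrichment_test(c(2, 2, 2), c(2, 2))$p.value, 1)
  expect_error(enrichment_test(numeric(0), 1), "non-empty")
})

test_that("planted conserved-element enrichment is detected", {
  sim <- simulate_species(small_spec(n_genes = 2000, n_causal = 200,
                                     n_qtls = 0, seed = 2020))
  x <- as.matrix(sim$features)
  causal <- rownames(x) %in% sim$causal
  res <- enrichment_test(x[causal, "CE_snp"], x[!causal, "CE_snp"])
  expect_lt(res$p.value, 0.05)
  pa <- enrichment_test(x[causal, "percent_absence"],
                        x[!causal, "percent_absence"])
  expect_lt(pa$p.value, 0.05)
  # an uninformative feature is not enriched at this n
  tf <- enrichment_test(x[causal, "TFBS_snp"], x[!causal, "TFBS_snp"])
  expect_gt(tf$p.value, 0.001)
})

test_that("expression overlap filter intersects rank and fold change", {
  ids <- paste0("g", 1:10)
  scores <- stats::setNames(seq(1, 0.1, length.out = 10), ids)
  r <- rank_qtl(scores, qtl_region("q", ids))
  fc <- data.frame(gene_id = ids,
                   fc_meristem = c(3, 0.5, 2.5, 1, 1, 1, 9, 1, 1, 1),
                   fc_elongation = c(0, 0, 0, 4, 0, 0, 0, 0, 0, 5))
  # top 20% of 10 genes = 2 genes; g1 (fc 3) and g2 (fc 0.5)
  got <- expression_overlap_filter(r, fc, cutoff_percent = 20,
                                   fc_threshold = 2)
  expect_equal(got, "g1", ignore_attr = TRUE)
  # top 40% holds g1..g4, of which g1, g3, g4 exceed 2-fold
  got4 <- expression_overlap_filter(r, fc, cutoff_percent = 40,
                                    fc_threshold = 2)
  expect_setequal(got4, c("g1", "g3", "g4"))
  # nothing above an extreme threshold
  expect_length(expression_overlap_filter(r, fc, 20, fc_threshold = 99), 0)
  # a vacuous threshold returns the whole top set
  expect_setequal(expression_overlap_filter(r, fc, 20, fc_threshold = -1),
                  c("g1", "g2"))
  # missing expression rows are excluded and reported
  miss <- expression_overlap_filter(r, fc[-1, ], 20, 2)
  expect_equal(attr(miss, "missing"), "g1")
  expect_length(miss, 0)
})

test_that("validation summary ties ranking and metrics together", {
  ids <- paste0("g", 1:20)
  scores <- stats::setNames(seq(1, 0, length.out = 20), ids)
  qtls <- list(qtl_region("qa", ids[1:10], causal_gene = "g1"),
               qtl_region("qb", ids[11:20], causal_gene = "g20"))
  v <- qtg_validate(scores, qtls, cutoffs = c(10, 100))
  expect_equal(v$detail$causal_percent_rank, c(10, 100))
  expect_equal(unname(v$recall), c(0.5, 1))
  expect_equal(unname(v$background), c(0.1, 1))
  expect_equal(unname(v$precision), c(0.5, c(1 / 10 + 1 / 10) / 2))
  expect_error(qtg_validate(scores, list(qtl_region("qc", ids[1:3]))),
               "no causal gene")
})

test_that("random scores recall causal genes at the background rate", {
  set.seed(99)
  n_qtl <- 10000
  sizes <- sample(seq(20, 700, by = 20), n_qtl, replace = TRUE)
  hit5 <- hit10 <- hit20 <- logical(n_qtl)
  for (i in seq_len(n_qtl)) {
    pr <- ceiling(100 * sample.int(sizes[i], 1) / sizes[i])
    hit5[i] <- pr <= 5; hit10[i] <- pr <= 10; hit20[i] <- pr <= 20
  }
  for (pair in list(list(hit5, 0.05), list(hit10, 0.10),
                    list(hit20, 0.20))) {
    se <- sqrt(pair[[2]] * (1 - pair[[2]]) / n_qtl)
    expect_lt(abs(mean(pair[[1]]) - pair[[2]]), 2 * se)
  }
})
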