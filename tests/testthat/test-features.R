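test_that("binary polymorphism features follow the effect schema", {
  genes <- mkgenes(c("g1", "g2", "g3"), c(0, 1000, 2000),
                   c(500, 1500, 2500))
  # 5 variants over 3 genes: 2 synonymous, 1 deleterious missense,
  # 1 frameshift indel, 1 intergenic
  v <- rbind(mkvar(10, "synonymous_variant", "g1"),
             mkvar(20, "synonymous_variant", "g1"),
             mkvar(1010, "missense_variant", "g2", deleterious = TRUE),
             mkvar(2010, "frameshift_variant", "g3", ref = "AT", alt = "A"),
             mkvar(5000, "intergenic_region"))
  ft <- encode_variant_features(v, genes)
  x <- as.matrix(ft)
  expect_equal(unname(x["g1", "is_synonymous"]), 1)
  expect_equal(unname(x["g2", "is_nonsyn_deleterious"]), 1)
  expect_equal(unname(x["g2", "is_nonsyn_tolerated"]), 0)
  expect_equal(unname(x["g3", "is_frameshift"]), 1)
  # everything not planted is 0
  expect_equal(sum(x), 3)
})

test_that("genes without variants get all-zero rows", {
  genes <- mkgenes("g1", 0, 100)
  ft <- encode_variant_features(mkvar(5000, "intergenic_region"), genes)
  expect_equal(sum(as.matrix(ft)), 0)
})

test_that("pathogenicity is never imputed for the nonsynonymous flags", {
  genes <- mkgenes("g1", 0, 100)
  # missense with no SIFT-style call matches neither rule
  ft <- encode_variant_features(mkvar(10, "missense_variant", "g1"), genes)
  expect_equal(sum(as.matrix(ft)), 0)
  expect_equal(attr(ft, "unmatched"), 1L)
  ft2 <- encode_variant_features(
    mkvar(10, "missense_variant", "g1", deleterious = FALSE), genes)
  expect_equal(unname(as.matrix(ft2)["g1", "is_nonsyn_tolerated"]), 1)
})

test_that("variants naming unknown genes are an error, unknown terms a counter", {
  genes <- mkgenes("g1", 0, 100)
  expect_error(
    encode_variant_features(mkvar(10, "missense_variant", "gX"), genes),
    "gX")
  ft <- encode_variant_features(
    mkvar(10, "weird_novel_effect", "g1"), genes)
  expect_equal(attr(ft, "unmatched"), 1L)
  expect_equal(sum(as.matrix(ft)), 0)
})

test_that("conserved-element counts match the worked overlap example", {
  genes <- mkgenes("g1", 5000, 8000)
  elems <- mkelems(4500, 4800, "CE")
  v <- rbind(mkvar(4600, "upstream_gene_variant"),
             mkvar(4700, "upstream_gene_variant"),
             mkvar(4750, "upstream_gene_variant", ref = "AT", alt = "A"))
  x <- as.matrix(count_cns_polymorphisms(v, elems, genes))
  expect_equal(unname(x["g1", "CE_snp"]), 2)
  expect_equal(unname(x["g1", "CE_indel"]), 1)
  expect_equal(unname(x["g1", "TFBS_snp"]), 0)
})

test_that("the 1 kb assignment window excludes distant elements", {
  genes <- mkgenes("g1", 5000, 8000)
  v <- mkvar(3600, "intergenic_region")
  # gap of 1500 bp: not assigned
  far <- as.matrix(count_cns_polymorphisms(v, mkelems(3400, 3500, "CE"),
                                           genes))
  expect_equal(sum(far), 0)
  # element ending exactly at the window edge does not overlap
  edge <- as.matrix(count_cns_polymorphisms(
    mkvar(3950, "x"), mkelems(3900, 4000, "CE"), genes))
  expect_equal(sum(edge), 0)
  # one bp inside the window does
  inside <- as.matrix(count_cns_polymorphisms(
    mkvar(4000, "x"), mkelems(3900, 4001, "CE"), genes))
  expect_equal(unname(inside["g1", "CE_snp"]), 1)
})

test_that("an element shared by two genes counts its variants for both", {
  genes <- mkgenes(c("g1", "g2"), c(5000, 9500), c(8000, 12000))
  elems <- mkelems(8500, 8700, "CE")   # within 1 kb of both genes
  v <- mkvar(8600, "intergenic_region")
  x <- as.matrix(count_cns_polymorphisms(v, elems, genes))
  expect_equal(unname(x[, "CE_snp"]), c(1, 1))
})

test_that("overlapping same-kind elements count a variant once per gene", {
  genes <- mkgenes("g1", 5000, 8000)
  elems <- mkelems(c(4500, 4550), c(4800, 4850), c("CE", "CE"))
  v <- mkvar(4600, "x")
  x <- as.matrix(count_cns_polymorphisms(v, elems, genes))
  expect_equal(unname(x["g1", "CE_snp"]), 1)
})

test_that("interval assignment matches a brute-force all-pairs scan", {
  set.seed(7)
  n_genes <- 40
  genes <- mkgenes(sprintf("g%02d", 1:n_genes),
                   starts = sort(sample.int(2e5, n_genes)) ,
                   ends = 0, chrom = sample(c("chr1", "chr2"), n_genes,
                                            replace = TRUE))
  genes$end <- genes$start + sample(500:3000, n_genes, replace = TRUE)
  ne <- 60
  elems <- mkelems(starts = sample.int(2e5, ne), ends = 0,
                   kinds = sample(c("CE", "TFBS"), ne, replace = TRUE),
                   chrom = sample(c("chr1", "chr2"), ne, replace = TRUE))
  elems$end <- elems$start + sample(50:500, ne, replace = TRUE)
  nv <- 150
  v <- do.call(rbind, lapply(seq_len(nv), function(i)
    mkvar(sample.int(2e5, 1), "x",
          chrom = sample(c("chr1", "chr2"), 1),
          ref = sample(c("A", "AT"), 1))))
  got <- as.matrix(count_cns_polymorphisms(v, elems, genes))
  want <- brute_force_cns_counts(v, elems, genes, window = 1000)
  expect_equal(got, want)
  # row order of the inputs never changes the result
  perm <- as.matrix(count_cns_polymorphisms(
    v[sample(nv), ], elems[sample(ne), ], genes))
  expect_equal(perm, got)
})

test_that("percent absence is the fraction of accessions lacking the gene", {
  pav <- matrix(1L, 3, 80, dimnames = list(c("g1", "g2", "g3"), NULL))
  colnames(pav) <- paste0("a", 1:80)
  pav["g2", 1:20] <- 0L   # absent in 20 of 80 accessions
  pav["g3", ] <- 0L
  x <- as.matrix(compute_percent_absence(pav))
  expect_equal(unname(x[, 1]), c(0, 0.25, 1))
  # duplicating every accession column leaves the fraction unchanged
  x2 <- as.matrix(compute_percent_absence(cbind(pav, pav)))
  expect_equal(unname(x2[, 1]), c(0, 0.25, 1))
})

test_that("GO slim aggregation sets function flags through ancestors", {
  genes <- mkgenes(c("g1", "g2", "g3", "g4"), 1:4 * 1000, 1:4 * 1000 + 100)
  slim_map <- list("GO:1" = c("GO:0005215"),
                   "GO:2" = c("GO:0003700", "GO:0099999"),
                   "GO:3" = c("GO:0099999"))
  ann <- list(g1 = "GO:1", g2 = c("GO:2", "GO:3"), g3 = "GO:3")
  x <- as.matrix(aggregate_go_features(ann, slim_map, genes))
  expected <- cbind(is_transporter = c(1, 0, 0, 0),
                    is_transcription_factor = c(0, 1, 0, 0))
  rownames(expected) <- genes$gene_id
  expect_equal(x, expected)
  # a term that is itself the slim term counts directly
  x2 <- as.matrix(aggregate_go_features(list(g1 = "GO:0005215"),
                                        slim_map, genes))
  expect_equal(unname(x2["g1", "is_transporter"]), 1)
  # unmapped IDs are diagnostics, not errors
  ft <- aggregate_go_features(list(g1 = "GO:unknown"), slim_map, genes)
  expect_equal(attr(ft, "unmapped_terms"), 1L)
})

test_that("paralog copy number comes from same-species orthogroup size", {
  genes <- mkgenes(c("g1", "g2", "g3", "g4"), 1:4 * 1000,
                   1:4 * 1000 + 100)
  og <- data.frame(
    orthogroup = c("OG1", "OG1", "OG1", "OG2", "OG2", rep("OG2", 4)),
    species = c("sp", "sp", "sp", "sp", "sp", rep("other", 4)),
    gene_id = c("g1", "g2", "dummy1", "g3", "dummy2", paste0("o", 1:4)),
    stringsAsFactors = FALSE)
  x <- as.matrix(attach_paralog_counts(og, genes, "sp"))
  # OG1 has 3 sp members, OG2 has 2 sp members (the 4 'other' genes do
  # not count), g4 is a singleton
  expect_equal(unname(x[, 1]), c(3, 3, 2, 1))
})

test_that("metabolic domain flags are one column per domain", {
  genes <- mkgenes(c("g1", "g2"), c(0, 1000), c(100, 1100))
  dom <- data.frame(gene_id = c("g1", "g1"),
                    domain = c("lipid", "amine"))
  x <- as.matrix(encode_metabolic_domains(dom, genes))
  expect_equal(colnames(x), c("domain_amine", "domain_lipid"))
  expect_equal(unname(x["g1", ]), c(1, 1))
  expect_equal(unname(x["g2", ]), c(0, 0))
})
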