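#' Construct a QTL region
#'
#' @param qtl_id identifier.
#' @param gene_ids character vector of the interval's genes (unique,
#'   non-empty).
#' @param causal_gene the validated causal gene, `NA` when unknown; must be
#'   one of `gene_ids` when set.
#' @param trait free-text trait label.
#' @return An object of class `qtg_qtl`.
#' @export
qtl_region <- function(qtl_id, gene_ids, causal_gene = NA_character_,
                       trait = "") {
  if (!length(gene_ids)) stop("QTL ", qtl_id, " has no genes")
  if (anyDuplicated(gene_ids))
    stop("QTL ", qtl_id, " has duplicate gene IDs")
  if (!is.na(causal_gene) && !(causal_gene %in% gene_ids))
    stop("causal gene ", causal_gene, " is not in QTL ", qtl_id)
  structure(list(qtl_id = qtl_id, trait = trait, gene_ids = gene_ids,
                 causal_gene = causal_gene), class = "qtg_qtl")
}

#' Rank the genes of a QTL interval by ensemble score
#'
#' Genes are sorted by score, best first; tied scores share the mean of
#' their rank span.  The percent rank is `ceiling(100 * rank / N)` so the
#' top gene of a large interval prints as 1% and "top 20%" of an N-gene
#' interval always means `ceiling(N / 5)` genes.
#'
#' @param scores named numeric vector of ensemble scores (e.g. from
#'   [predict.qtg_model()]) covering every gene of the QTL.
#' @param qtl a `qtg_qtl` object.
#' @return data.frame (class `qtg_rank`) with columns `gene_id`, `score`,
#'   `rank`, `percent_rank`, sorted by rank, plus attributes `qtl_id` and
#'   `causal_gene`.
#' @export
rank_qtl <- function(scores, qtl) {
  missing <- setdiff(qtl$gene_ids, names(scores))
  if (length(missing))
    stop("no score for gene(s) in QTL ", qtl$qtl_id, ": ",
         paste(missing, collapse = ", "))
  s <- scores[qtl$gene_ids]
  rk <- rank(-s, ties.method = "average")
  out <- data.frame(gene_id = qtl$gene_ids, score = unname(s),
                    rank = unname(rk),
                    percent_rank = ceiling(100 * unname(rk) / length(s)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank, out$gene_id), ]
  rownames(out) <- NULL
  structure(out, qtl_id = qtl$qtl_id, causal_gene = qtl$causal_gene,
            class = c("qtg_rank", "data.frame"))
}

#' Recall of causal genes at top-percent cutoffs
#'
#' The fraction of validation QTLs whose causal gene has a percent rank at
#' or below each cutoff (a causal gene ranked exactly at the cutoff counts
#' as recalled).
#'
#' @param percent_ranks numeric vector, the causal gene's percent rank in
#'   each validation QTL.
#' @param cutoffs percent cutoffs.
#' @return Named numeric vector of recall fractions, one per cutoff.
#' @export
recall_at_cutoffs <- function(percent_ranks, cutoffs = c(5, 10, 20)) {
  stats::setNames(vapply(cutoffs, function(f) mean(percent_ranks <= f),
                         numeric(1)),
                  paste0("top", cutoffs))
}

#' Average per-QTL precision at top-percent cutoffs
#'
#' For a QTL with N genes, prioritizing the top f% means selecting
#' `ceiling(f/100 * N)` genes; its precision is 1 over that count when the
#' causal gene is among them and 0 otherwise.  The summary averages the
#' per-QTL precisions.
#'
#' @param n_genes integer vector, genes per validation QTL.
#' @param percent_ranks causal-gene percent rank per QTL (same order).
#' @param cutoffs percent cutoffs.
#' @return Named numeric vector of average precisions, one per cutoff.
#' @export
average_precision_at_cutoffs <- function(n_genes, percent_ranks,
                                         cutoffs = c(5, 10, 20)) {
  stopifnot(length(n_genes) == length(percent_ranks))
  out <- vapply(cutoffs, function(f) {
    prioritized <- ceiling(f / 100 * n_genes)
    mean(ifelse(percent_ranks <= f, 1 / prioritized, 0))
  }, numeric(1))
  stats::setNames(out, paste0("top", cutoffs))
}

#' Theoretical background recall at a top-percent cutoff
#'
#' The probability that a random selection of f% of a QTL's genes contains
#' the causal gene: f/100.
#'
#' @param f percent cutoff in (0, 100].
#' @return `f / 100`.
#' @export
theoretical_background <- function(f) {
  if (any(f <= 0 | f > 100)) stop("cutoff must be in (0, 100]")
  f / 100
}

#' Compare two models' validation outcomes with Fisher's exact test
#'
#' Each model contributes (recalled, not recalled) counts of validation
#' causal genes at one cutoff; the two-sided exact test asks whether the
#' recall proportions differ.
#'
#' @param counts_a,counts_b integer vectors `c(recalled, not_recalled)`.
#' @return Two-sided p-value.  A degenerate table (a zero margin) returns
#'   1 with a warning.
#' @export
fisher_compare <- function(counts_a, counts_b) {
  stopifnot(length(counts_a) == 2, length(counts_b) == 2,
            all(c(counts_a, counts_b) >= 0))
  m <- rbind(counts_a, counts_b)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    warning("degenerate 2x2 table (zero margin); p = 1")
    return(1)
  }
  stats::fisher.test(m)$p.value
}

#' Mann-Whitney enrichment test: causal genes vs genome background
#'
#' Two-sided rank-sum test of whether a feature's values differ between
#' causal genes and the genome.  For small pooled samples the p-value is
#' computed by exhaustive enumeration of all group assignments of the
#' pooled values (exact even under ties); larger samples use the
#' tie-corrected normal approximation of [stats::wilcox.test()].
#'
#' @param causal_values feature values of the causal genes.
#' @param genome_values feature values of the background genes.
#' @param exact_max enumerate exactly when `choose(n1+n2, n1)` is at most
#'   this.
#' @return List with `statistic` (the U statistic for the causal group,
#'   ties counted half) and `p.value`.
#' @export
enrichment_test <- function(causal_values, genome_values,
                            exact_max = 50000) {
  n1 <- length(causal_values); n2 <- length(genome_values)
  if (!n1 || !n2) stop("both samples must be non-empty")
  pooled <- c(causal_values, genome_values)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (length(unique(pooled)) == 1L)
    return(list(statistic = u, p.value = 1))
  if (choose(n1 + n2, n1) <= exact_max) {
    mu <- n1 * n2 / 2
    combos <- utils::combn(n1 + n2, n1)
    us <- apply(combos, 2, function(idx)
      sum(r[idx]) - n1 * (n1 + 1) / 2)
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    return(list(statistic = u, p.value = p))
  }
  w <- suppressWarnings(stats::wilcox.test(causal_values, genome_values,
                                           exact = FALSE, correct = TRUE))
  list(statistic = u, p.value = w$p.value)
}

#' Intersect top-ranked QTL genes with expression-based candidates
#'
#' Keeps the genes of a ranked QTL that are both within the top
#' `cutoff_percent` and up-regulated more than `fc_threshold`-fold in the
#' internode meristem or cell-elongation zone relative to the maturation
#' zone.  Genes without expression data are excluded (observed sets are
#' intersected, nothing is imputed) and listed in the `"missing"`
#' attribute.
#'
#' @param rank_result a `qtg_rank` data.frame from [rank_qtl()].
#' @param fold_changes data.frame with columns `gene_id`, `fc_meristem`,
#'   `fc_elongation`.
#' @param cutoff_percent percent-rank cutoff.
#' @param fc_threshold fold-change threshold (strict).
#' @return Character vector of candidate gene IDs, with attribute
#'   `missing` listing top-ranked genes lacking expression data.
#' @export
expression_overlap_filter <- function(rank_result, fold_changes,
                                      cutoff_percent = 20,
                                      fc_threshold = 2.0) {
  top <- rank_result$gene_id[rank_result$percent_rank <= cutoff_percent]
  fc <- fold_changes[match(top, fold_changes$gene_id), , drop = FALSE]
  missing <- top[is.na(fc$gene_id)]
  keep <- !is.na(fc$gene_id) &
    (fc$fc_meristem > fc_threshold | fc$fc_elongation > fc_threshold)
  out <- top[keep]
  attr(out, "missing") <- missing
  out
}

#' External validation of a model over QTLs with known causal genes
#'
#' Ranks every QTL, locates the causal gene's percent rank, and summarizes
#' recall and average precision at the cutoffs, next to the theoretical
#' background.
#'
#' @param scores named ensemble scores covering all QTL genes.
#' @param qtls list of `qtg_qtl` objects, each with a known causal gene.
#' @param cutoffs percent cutoffs.
#' @return Object of class `qtg_validation`: list with `detail` (per-QTL
#'   data.frame), `recall`, `precision`, `background` and `ranks` (the
#'   per-QTL `qtg_rank` objects).
#' @export
qtg_validate <- function(scores, qtls, cutoffs = c(5, 10, 20)) {
  if (!length(qtls)) stop("no validation QTLs")
  ranks <- lapply(qtls, function(q) {
    if (is.na(q$causal_gene))
      stop("QTL ", q$qtl_id, " has no causal gene; cannot validate")
    rank_qtl(scores, q)
  })
  detail <- do.call(rbind, lapply(ranks, function(r) {
    causal <- attr(r, "causal_gene")
    data.frame(qtl_id = attr(r, "qtl_id"),
               n_genes = nrow(r),
               causal_gene = causal,
               causal_percent_rank = r$percent_rank[r$gene_id == causal],
               stringsAsFactors = FALSE)
  }))
  rownames(detail) <- NULL
  structure(list(
    detail = detail,
    recall = recall_at_cutoffs(detail$causal_percent_rank, cutoffs),
    precision = average_precision_at_cutoffs(detail$n_genes,
                                             detail$causal_percent_rank,
                                             cutoffs),
    background = stats::setNames(theoretical_background(cutoffs),
                                 paste0("top", cutoffs)),
    cutoffs = cutoffs, ranks = ranks), class = "qtg_validation")
}

#' @export
print.qtg_validation <- function(x, ...) {
  cat("External validation over", nrow(x$detail), "QTLs\n")
  m <- rbind(recall = x$recall, avg_precision = round(x$precision, 3),
             background = x$background)
  print(m)
  invisible(x)
}

#' Curated sorghum QTL validation set
#'
#' The ten literature-curated sorghum QTLs with cloned causal genes that
#' ship with the package (trait, gene name and ID, interval gene count and
#' the causal gene's published percent rank under the sorghum model).
#'
#' @return data.frame with columns `trait`, `gene_name`, `gene_id`,
#'   `genes_in_qtl`, `percent_rank`.
#' @export
sorghum_validation_table <- function() {
  read_tsv(system.file("extdata", "sorghum_validation_table.tsv",
                       package = "qtgrank", mustWork = TRUE))
}
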