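# Independent oracles and small fixture builders shared across tests.

# AUC as explicit pair concordance: ties count one half.
brute_force_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

# All-pairs interval scan for conserved-element assignment and variant
# counting (0-based half-open coordinates throughout).  Each distinct
# variant counts once per gene per element kind.
brute_force_cns_counts <- function(variants, elements, genes, window) {
  out <- matrix(0, nrow(genes), 4,
                dimnames = list(genes$gene_id,
                                c("CE_snp", "TFBS_snp", "CE_indel",
                                  "TFBS_indel")))
  v <- unique(variants[, c("chrom", "pos", "ref", "alt", "variant_class")])
  for (gi in seq_len(nrow(genes))) {
    lo <- genes$start[gi] - window
    hi <- genes$end[gi] + window
    for (kind in c("CE", "TFBS")) {
      in_any <- rep(FALSE, nrow(v))
      for (ei in which(elements$kind == kind)) {
        if (elements$chrom[ei] != genes$chrom[gi]) next
        if (elements$end[ei] <= lo || elements$start[ei] >= hi) next
        in_any <- in_any |
          (v$chrom == elements$chrom[ei] & v$pos >= elements$start[ei] &
             v$pos < elements$end[ei])
      }
      out[gi, paste0(kind, "_snp")] <-
        sum(in_any & v$variant_class == "SNP")
      out[gi, paste0(kind, "_indel")] <-
        sum(in_any & v$variant_class == "indel")
    }
  }
  out
}

# Exact two-sided Fisher p by full hypergeometric enumeration
# (point-probability method: sum the probabilities of all tables with
# fixed margins no more probable than the observed one).
enumerate_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled values to the two groups; U computed by direct pair comparison.
enumerate_mw <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); n <- length(pooled)
  u_of <- function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    total <- 0
    for (p in a) for (q in b) total <- total + (p > q) + 0.5 * (p == q)
    total
  }
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * (n - n1) / 2
  us <- apply(utils::combn(n, n1), 2, u_of)
  list(statistic = u_obs,
       p.value = mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9))
}

# Small hand-constructed feature table.
toy_features <- function() {
  m <- cbind(signal = c(1, 1, 1, 0, 0, 0, 1, 0),
             noise = c(0, 1, 0, 1, 1, 0, 0, 1))
  rownames(m) <- paste0("g", 1:8)
  qtg_features(m, kinds = "binary")
}

# Separable table: feature 'x' alone distinguishes the positives.
separable_features <- function(n = 60, seed = 42) {
  set.seed(seed)
  pos <- paste0("p", seq_len(n / 2))
  neg <- paste0("n", seq_len(n / 2))
  m <- cbind(x = c(rep(1, n / 2), rep(0, n / 2)),
             z = rbinom(n, 1, 0.5))
  rownames(m) <- c(pos, neg)
  list(features = qtg_features(m, kinds = "binary"), positives = pos)
}

# Published sorghum external-validation table (interval sizes and causal
# percent ranks of the ten curated QTLs).
sorghum_table <- function() sorghum_validation_table()

small_spec <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 300, n_causal = 30, n_qtls = 4,
         genes_per_qtl = c(10, 60), seed = 101), list(...))
  do.call(fixture_spec, args)
}
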