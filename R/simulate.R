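#' Default feature generating distributions for synthetic species
#'
#' One entry per simulated feature: the sampling family, its background
#' (null) parameters, and, for features carrying causal signal, the
#' causal-gene parameters.  The planted effects mirror the enrichment seen
#' in real panels: causal genes have more SNPs/indels in nearby conserved
#' elements (Poisson mean 0.5 vs 1.5 for `CE_snp`), higher gene absence
#' across accessions (mean 2% vs 10%), an enriched deleterious
#' nonsynonymous flag (odds x4) and a mildly higher paralog copy number.
#' Polymorphisms in transcription-factor binding sites and the function
#' flags carry no signal by default.
#'
#' @return Named list of per-feature sampling specifications.
#' @export
default_feature_spec <- function() {
  list(
    is_nonsyn_deleterious = list(kind = "binary", dist = "bernoulli",
                                 p0 = 0.10, odds_mult = 4),
    is_synonymous = list(kind = "binary", dist = "bernoulli", p0 = 0.50),
    is_frameshift = list(kind = "binary", dist = "bernoulli", p0 = 0.05),
    is_intron     = list(kind = "binary", dist = "bernoulli", p0 = 0.40),
    CE_snp     = list(kind = "count", dist = "poisson",
                      lambda0 = 0.5, lambda1 = 1.5),
    TFBS_snp   = list(kind = "count", dist = "poisson", lambda0 = 0.3),
    CE_indel   = list(kind = "count", dist = "poisson",
                      lambda0 = 0.2, lambda1 = 0.4),
    TFBS_indel = list(kind = "count", dist = "poisson", lambda0 = 0.1),
    percent_absence = list(kind = "fraction", dist = "betabinom",
                           mean0 = 0.02, mean1 = 0.10, shape = 0.5),
    paralog_copy_number = list(kind = "count", dist = "one_plus_poisson",
                               lambda0 = 1, lambda1 = 2),
    is_transporter = list(kind = "binary", dist = "bernoulli", p0 = 0.10),
    is_transcription_factor = list(kind = "binary", dist = "bernoulli",
                                   p0 = 0.10)
  )
}

#' Specification of a synthetic species
#'
#' Collects the study conditions under which synthetic data are drawn:
#' genome size, number of causal genes, accession panel size, QTL layout
#' and the per-feature generating distributions.  `effect_scale`
#' interpolates every planted effect between the null (0) and its default
#' strength (1), which is how effect-size sweeps are expressed.
#'
#' @param n_genes genes in the synthetic genome.
#' @param n_causal causal genes (drawn from the causal feature
#'   distributions and labelled).
#' @param n_causal_like additional genes drawn from the causal
#'   distributions but left unlabelled; used as cross-species ortholog
#'   targets by [simulate_ortholog_pair()].
#' @param n_accessions accessions in the presence/absence panel.
#' @param n_qtls synthetic QTL intervals to lay out.
#' @param genes_per_qtl integer range of QTL sizes (genes), drawn
#'   uniformly; the default 20-700 spans the interval sizes reported for
#'   curated sorghum QTLs.
#' @param species species label used in the orthogroup/causal tables.
#' @param effect_scale multiplier interpolating planted effect sizes
#'   (0 = null model).
#' @param feature_spec per-feature distributions, see
#'   [default_feature_spec()].
#' @param seed integer seed; identical specs yield identical fixtures.
#' @return Object of class `qtg_fixture_spec`.
#' @export
fixture_spec <- function(n_genes = 2000, n_causal = round(n_genes / 10),
                         n_causal_like = 0, n_accessions = 80,
                         n_qtls = 10, genes_per_qtl = c(20, 700),
                         species = "synthA", effect_scale = 1,
                         feature_spec = default_feature_spec(),
                         seed = 20200518) {
  stopifnot(n_causal + n_causal_like < n_genes, n_accessions >= 1,
            length(genes_per_qtl) == 2, genes_per_qtl[1] >= 1,
            effect_scale >= 0)
  for (nm in names(feature_spec)) {
    fs <- feature_spec[[nm]]
    if (fs$dist == "bernoulli") {
      p1 <- bernoulli_causal_p(fs, effect_scale)
      if (fs$p0 <= 0 || fs$p0 >= 1 || p1 <= 0 || p1 >= 1)
        stop("infeasible Bernoulli parameters for feature ", nm)
    }
    if (fs$dist %in% c("poisson", "one_plus_poisson")) {
      if (fs$lambda0 < 0 || poisson_causal_lambda(fs, effect_scale) < 0)
        stop("infeasible Poisson mean for feature ", nm)
    }
    if (fs$dist == "betabinom") {
      m1 <- fs$mean0 + effect_scale * (default0(fs$mean1, fs$mean0) - fs$mean0)
      if (fs$mean0 <= 0 || fs$mean0 >= 1 || m1 <= 0 || m1 >= 1)
        stop("infeasible Beta mean for feature ", nm)
    }
  }
  structure(list(n_genes = n_genes, n_causal = n_causal,
                 n_causal_like = n_causal_like,
                 n_accessions = n_accessions, n_qtls = n_qtls,
                 genes_per_qtl = genes_per_qtl, species = species,
                 effect_scale = effect_scale, feature_spec = feature_spec,
                 seed = seed),
            class = "qtg_fixture_spec")
}

default0 <- function(x, fallback) if (is.null(x)) fallback else x

bernoulli_causal_p <- function(fs, s) {
  mult <- default0(fs$odds_mult, 1)^s
  odds <- mult * fs$p0 / (1 - fs$p0)
  odds / (1 + odds)
}

poisson_causal_lambda <- function(fs, s) {
  fs$lambda0 + s * (default0(fs$lambda1, fs$lambda0) - fs$lambda0)
}

#' Simulate a synthetic species
#'
#' Draws a per-gene feature table under the spec's distributions (causal
#' genes from the causal parameters, the rest from the null), lays genes
#' out on synthetic chromosomes, and places contiguous-block QTL
#' intervals each seeded with one designated causal gene.  The companion
#' [write_species_files()] encodes the same values as the raw file formats
#' the extraction pipeline ingests, and extraction reproduces the feature
#' table exactly.
#'
#' The binary flags `is_upstream`/`is_downstream` are derived, not
#' sampled: they record whether the gene has any variant in an assigned
#' conserved element (placed upstream) or binding site (placed
#' downstream), mirroring how effect annotation would flag those variants.
#'
#' @param spec a `qtg_fixture_spec`.
#' @return List with `features` (`qtg_features` over the full extraction
#'   feature set), `causal` (labelled causal gene IDs), `causal_like`
#'   (unlabelled causal-distributed gene IDs), `qtls` (list of `qtg_qtl`),
#'   `genes` (gene-model data.frame), `pav` (presence/absence matrix) and
#'   `spec`.
#' @export
simulate_species <- function(spec) {
  stopifnot(inherits(spec, "qtg_fixture_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  n <- spec$n_genes
  ids <- sprintf("%s.g%05d", spec$species, seq_len(n))
  per_chrom <- 500L
  j <- (seq_len(n) - 1L) %% per_chrom
  genes <- data.frame(
    gene_id = ids,
    chrom = sprintf("chr%d", (seq_len(n) - 1L) %/% per_chrom + 1L),
    start = j * 10000L + 2000L,
    end = j * 10000L + 4000L,
    strand = "+", stringsAsFactors = FALSE)

  n_signal <- spec$n_causal + spec$n_causal_like
  signal <- sample(n, n_signal)
  causal_idx <- signal[seq_len(spec$n_causal)]
  causal_like_idx <- setdiff(signal, causal_idx)

  s <- spec$effect_scale
  sampled <- lapply(names(spec$feature_spec), function(nm) {
    fs <- spec$feature_spec[[nm]]
    v <- switch(fs$dist,
      bernoulli = {
        p <- rep(fs$p0, n); p[signal] <- bernoulli_causal_p(fs, s)
        stats::rbinom(n, 1, p)
      },
      poisson = {
        lam <- rep(fs$lambda0, n)
        lam[signal] <- poisson_causal_lambda(fs, s)
        stats::rpois(n, lam)
      },
      one_plus_poisson = {
        lam <- rep(fs$lambda0, n)
        lam[signal] <- poisson_causal_lambda(fs, s)
        1L + stats::rpois(n, lam)
      },
      betabinom = {
        m <- rep(fs$mean0, n)
        m[signal] <- fs$mean0 + s * (default0(fs$mean1, fs$mean0) - fs$mean0)
        p <- stats::rbeta(n, fs$shape, fs$shape * (1 - m) / m)
        stats::rbinom(n, spec$n_accessions, p)  # absent-accession count
      },
      stop("unknown distribution '", fs$dist, "'"))
    v
  })
  names(sampled) <- names(spec$feature_spec)

  # presence/absence panel: gene absent in the first k accessions
  k_absent <- sampled$percent_absence
  pav <- matrix(1L, nrow = n, ncol = spec$n_accessions,
                dimnames = list(ids, sprintf("acc%03d",
                                             seq_len(spec$n_accessions))))
  for (i in which(k_absent > 0)) pav[i, seq_len(k_absent[i])] <- 0L

  # full extraction-ordered table; unplanted effect classes stay all-zero
  schema_names <- names(default_effect_schema())
  m <- matrix(0, nrow = n, ncol = 0)
  bin <- matrix(0, nrow = n, ncol = length(schema_names),
                dimnames = list(ids, schema_names))
  for (nm in c("is_nonsyn_deleterious", "is_synonymous", "is_frameshift",
               "is_intron"))
    bin[, nm] <- sampled[[nm]]
  bin[, "is_upstream"] <- as.numeric(sampled$CE_snp + sampled$CE_indel > 0)
  bin[, "is_downstream"] <-
    as.numeric(sampled$TFBS_snp + sampled$TFBS_indel > 0)
  counts <- cbind(CE_snp = sampled$CE_snp, TFBS_snp = sampled$TFBS_snp,
                  CE_indel = sampled$CE_indel,
                  TFBS_indel = sampled$TFBS_indel) + 0
  rownames(counts) <- ids
  pa <- matrix(rowMeans(pav == 0L), ncol = 1,
               dimnames = list(ids, "percent_absence"))
  go <- cbind(is_transporter = sampled$is_transporter + 0,
              is_transcription_factor =
                sampled$is_transcription_factor + 0)
  rownames(go) <- ids
  par_cn <- matrix(sampled$paralog_copy_number + 0, ncol = 1,
                   dimnames = list(ids, "paralog_copy_number"))
  features <- merge_feature_fragments(list(
    qtg_features(bin, "binary"),
    qtg_features(counts, "count"),
    qtg_features(pa, "fraction"),
    qtg_features(go, "binary"),
    qtg_features(par_cn, "count")), ids)

  qtls <- list()
  if (spec$n_qtls > 0) {
    if (!spec$n_causal) stop("QTL layout needs at least one causal gene")
    size_range <- seq(spec$genes_per_qtl[1], min(spec$genes_per_qtl[2], n))
    sizes <- size_range[sample.int(length(size_range), spec$n_qtls,
                                   replace = TRUE)]
    seeds <- causal_idx[sample.int(length(causal_idx), spec$n_qtls,
                                   replace = spec$n_qtls > length(causal_idx))]
    qtls <- lapply(seq_len(spec$n_qtls), function(q) {
      mqtl <- sizes[q]; cidx <- seeds[q]
      lo <- max(1L, cidx - mqtl + 1L)
      hi <- min(cidx, n - mqtl + 1L)
      start <- if (lo >= hi) lo else sample(lo:hi, 1)
      qtl_region(sprintf("qtl%02d", q),
                 ids[start:(start + mqtl - 1L)],
                 causal_gene = ids[cidx],
                 trait = "synthetic trait")
    })
    names(qtls) <- vapply(qtls, `[[`, "", "qtl_id")
  }

  list(features = features, causal = ids[sort(causal_idx)],
       causal_like = ids[sort(causal_like_idx)], qtls = qtls,
       genes = genes, pav = pav, spec = spec)
}

#' Write a simulated species as the raw pipeline input files
#'
#' Encodes the simulated feature table as GFF3 gene models, an
#' effect-annotated VCF, a conserved-element table, a presence/absence
#' matrix, GO annotation and slim-mapping tables, an orthogroup table and
#' QTL/causal-gene lists.  Running [build_feature_table()] on the emitted
#' files reproduces `sim$features` exactly.
#'
#' @param sim result of [simulate_species()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the file paths, invisibly.
#' @export
write_species_files <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(gff = file.path(dir, "genes.gff3"),
         vcf = file.path(dir, "variants.vcf"),
         elements = file.path(dir, "elements.tsv"),
         pav = file.path(dir, "pav.tsv"),
         go = file.path(dir, "go.tsv"),
         slim = file.path(dir, "slim.tsv"),
         orthogroups = file.path(dir, "orthogroups.tsv"),
         causal = file.path(dir, "causal.tsv"),
         qtls = file.path(dir, "qtls.tsv"))
  g <- sim$genes
  x <- as.matrix(sim$features)

  writeLines(c("##gff-version 3",
               sprintf("%s\tqtgsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom, g$start + 1L, g$end, g$strand, g$gene_id)),
             p["gff"])

  vcf <- character(0)
  elem <- character(0)
  snp_ann <- function(gene, effect, pos0, sift = NULL) {
    info <- sprintf("ANN=G|%s|MODIFIER|%s|%s", effect, gene, gene)
    if (!is.null(sift)) info <- paste0(info, ";SIFT=", sift)
    sprintf("%s\t%d\t.\tA\tG\t.\tPASS\t%s",
            g$chrom[match(gene, g$gene_id)], pos0 + 1L, info)
  }
  indel_ann <- function(gene, effect, pos0) {
    sprintf("%s\t%d\t.\tAT\tA\t.\tPASS\tANN=A|%s|MODIFIER|%s|%s",
            g$chrom[match(gene, g$gene_id)], pos0 + 1L, effect, gene, gene)
  }
  for (i in seq_len(nrow(g))) {
    id <- g$gene_id[i]; s0 <- g$start[i]; e0 <- g$end[i]
    if (x[i, "is_nonsyn_deleterious"] == 1)
      vcf <- c(vcf, snp_ann(id, "missense_variant", s0 + 100L,
                            sift = "deleterious(0.01)"))
    if (x[i, "is_synonymous"] == 1)
      vcf <- c(vcf, snp_ann(id, "synonymous_variant", s0 + 200L))
    if (x[i, "is_frameshift"] == 1)
      vcf <- c(vcf, indel_ann(id, "frameshift_variant", s0 + 300L))
    if (x[i, "is_intron"] == 1)
      vcf <- c(vcf, snp_ann(id, "intron_variant", s0 + 400L))
    n_ce <- x[i, "CE_snp"] + x[i, "CE_indel"]
    if (n_ce > 0) {
      elem <- c(elem, sprintf("CE_%s\t%s\t%d\t%d\tCE", id, g$chrom[i],
                              s0 - 800L, s0 - 300L))
      if (x[i, "CE_snp"] > 0)
        vcf <- c(vcf, vapply(seq_len(x[i, "CE_snp"]), function(k)
          snp_ann(id, "upstream_gene_variant", s0 - 790L + 5L * k), ""))
      if (x[i, "CE_indel"] > 0)
        vcf <- c(vcf, vapply(seq_len(x[i, "CE_indel"]), function(k)
          indel_ann(id, "upstream_gene_variant", s0 - 500L + 5L * k), ""))
    }
    n_tf <- x[i, "TFBS_snp"] + x[i, "TFBS_indel"]
    if (n_tf > 0) {
      elem <- c(elem, sprintf("TFBS_%s\t%s\t%d\t%d\tTFBS", id, g$chrom[i],
                              e0 + 300L, e0 + 800L))
      if (x[i, "TFBS_snp"] > 0)
        vcf <- c(vcf, vapply(seq_len(x[i, "TFBS_snp"]), function(k)
          snp_ann(id, "downstream_gene_variant", e0 + 310L + 5L * k), ""))
      if (x[i, "TFBS_indel"] > 0)
        vcf <- c(vcf, vapply(seq_len(x[i, "TFBS_indel"]), function(k)
          indel_ann(id, "downstream_gene_variant", e0 + 600L + 5L * k), ""))
    }
  }
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations\">",
               "##INFO=<ID=SIFT,Number=1,Type=String,Description=\"SIFT-style call\">",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", sep = "\t"),
               vcf), p["vcf"])
  writeLines(c("element_id\tchrom\tstart\tend\tkind", elem), p["elements"])

  write_tsv(data.frame(gene_id = rownames(sim$pav), sim$pav,
                       check.names = FALSE), p["pav"])

  go_rows <- rbind(
    data.frame(gene_id = g$gene_id[x[, "is_transporter"] == 1],
               go_id = "GO:0008324", stringsAsFactors = FALSE),
    data.frame(gene_id = g$gene_id[x[, "is_transcription_factor"] == 1],
               go_id = "GO:0043565", stringsAsFactors = FALSE))
  write_tsv(go_rows, p["go"])
  write_tsv(data.frame(go_id = c("GO:0008324", "GO:0043565"),
                       slim_id = c("GO:0005215", "GO:0003700")), p["slim"])

  multi <- which(x[, "paralog_copy_number"] > 1)
  og_rows <- do.call(rbind, c(list(
    data.frame(orthogroup = character(0), species = character(0),
               gene_id = character(0))),
    lapply(multi, function(i) {
      cn <- x[i, "paralog_copy_number"]
      data.frame(orthogroup = paste0("OG_", g$gene_id[i]),
                 species = sim$spec$species,
                 gene_id = c(g$gene_id[i],
                             paste0(g$gene_id[i], ".p", seq_len(cn - 1) + 1)),
                 stringsAsFactors = FALSE)
    })))
  write_tsv(og_rows, p["orthogroups"])

  write_tsv(data.frame(gene_id = sim$causal, species = sim$spec$species,
                       trait = "synthetic trait", source = "simulated"),
            p["causal"])
  write_tsv(data.frame(
    qtl_id = names(sim$qtls),
    trait = vapply(sim$qtls, `[[`, "", "trait"),
    gene_ids = vapply(sim$qtls, function(q)
      paste(q$gene_ids, collapse = ","), ""),
    causal_gene = vapply(sim$qtls, `[[`, "", "causal_gene")), p["qtls"])
  invisible(p)
}

#' Simulate a species pair linked by an ortholog map
#'
#' Species A carries labelled causal genes; species B carries its own
#' labelled causal genes plus, for a fraction `overlap` of A's causal
#' genes, unlabelled ortholog target genes drawn from the causal feature
#' distribution.  The remaining A causal genes are mapped to random
#' background B genes, so at `overlap = 0` the transferred training set
#' carries no signal.  All map entries are recorded as fine-grained
#' orthology calls.
#'
#' @param spec_a,spec_b fixture specs for the two species (give them
#'   different `species` labels and seeds).
#' @param overlap fraction of A's causal genes whose B ortholog is
#'   causal-like, in \[0, 1\].
#' @return List with `a`, `b` (simulated species), `omap` (ortholog-map
#'   data.frame) and `causal` (A's causal-gene records for
#'   [expand_training_set()]).
#' @export
simulate_ortholog_pair <- function(spec_a, spec_b, overlap = 1) {
  stopifnot(overlap >= 0, overlap <= 1)
  sim_a <- simulate_species(spec_a)
  n_link <- round(overlap * length(sim_a$causal))
  spec_b$n_causal_like <- n_link
  sim_b <- simulate_species(spec_b)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seeds(spec_b$seed, 3)[3])
  linked <- sample(sim_a$causal, n_link)
  unlinked <- setdiff(sim_a$causal, linked)
  background <- setdiff(feature_genes(sim_b$features),
                        c(sim_b$causal, sim_b$causal_like))
  omap <- data.frame(
    causal_id = c(linked, unlinked),
    causal_species = spec_a$species,
    ortholog_id = c(sim_b$causal_like,
                    sample(background, length(unlinked))),
    ortholog_species = spec_b$species,
    kind = "fine_grained", stringsAsFactors = FALSE)
  causal <- data.frame(gene_id = sim_a$causal, species = spec_a$species,
                       stringsAsFactors = FALSE)
  list(a = sim_a, b = sim_b, omap = omap, causal = causal)
}
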