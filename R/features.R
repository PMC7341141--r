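#' Binary polymorphism features from effect-annotated variants
#'
#' Applies an effect-term schema to per-gene variant annotations: a feature
#' is 1 for a gene iff at least one of its variants matches the mapped
#' effect category (and, for the nonsynonymous features, the required
#' SIFT-style call), otherwise 0.  Genes without variants get all-zero
#' rows.  Variants whose effect terms match no schema rule (including
#' missense variants lacking a pathogenicity call) are skipped and counted
#' in the `"unmatched"` attribute of the result — a large count signals an
#' annotation-dialect/schema mismatch.
#'
#' @param variants data.frame as from [read_annotated_variants()].
#' @param genes data.frame of gene models as from [read_gene_models()]
#'   (only `gene_id` is used here).
#' @param schema effect schema, see [default_effect_schema()].
#' @return `qtg_features` fragment of binary features, one per schema rule,
#'   with attribute `unmatched` (number of skipped gene-linked variant
#'   annotations).
#' @export
encode_variant_features <- function(variants, genes,
                                    schema = default_effect_schema()) {
  validate_effect_schema(schema)
  m <- matrix(0, nrow = nrow(genes), ncol = length(schema),
              dimnames = list(genes$gene_id, names(schema)))
  unmatched <- 0L
  linked <- variants[!is.na(variants$gene_id), , drop = FALSE]
  unknown <- setdiff(linked$gene_id, genes$gene_id)
  if (length(unknown))
    stop("variant annotation references unknown gene(s): ",
         paste(unique(unknown), collapse = ", "))
  for (i in seq_len(nrow(linked))) {
    terms <- strsplit(linked$effects[i], "&", fixed = TRUE)[[1]]
    del <- linked$deleterious[i]
    hit <- FALSE
    for (feat in names(schema)) {
      rule <- schema[[feat]]
      if (!any(terms %in% rule$terms)) next
      if (!is.na(rule$deleterious) &&
          !identical(rule$deleterious, del)) next
      m[linked$gene_id[i], feat] <- 1
      hit <- TRUE
    }
    if (!hit) unmatched <- unmatched + 1L
  }
  out <- qtg_features(m, kinds = "binary")
  attr(out, "unmatched") <- unmatched
  out
}

#' Count variants in conserved non-coding elements near genes
#'
#' An element is assigned to every gene whose interval, extended by
#' `window` bp on both flanks, it overlaps (the flank is strand-agnostic).
#' For each gene the features `CE_snp`, `TFBS_snp`, `CE_indel` and
#' `TFBS_indel` count the distinct variants of the matching class that fall
#' inside any assigned element of the matching kind.  A variant inside an
#' element assigned to two genes counts for both genes; a variant covered
#' by several same-kind elements of one gene counts once.
#'
#' @param variants data.frame as from [read_annotated_variants()];
#'   duplicate annotation rows for one physical variant are collapsed.
#' @param elements data.frame as from [read_conserved_elements()].
#' @param genes data.frame as from [read_gene_models()].
#' @param window flank size in bp (default 1000).
#' @return `qtg_features` fragment with the four count features.
#' @export
count_cns_polymorphisms <- function(variants, elements, genes,
                                    window = 1000L) {
  stopifnot(window >= 0)
  features <- c("CE_snp", "TFBS_snp", "CE_indel", "TFBS_indel")
  m <- matrix(0L, nrow = nrow(genes), ncol = 4L,
              dimnames = list(genes$gene_id, features))
  if (nrow(elements) && nrow(variants)) {
    v <- unique(variants[, c("chrom", "pos", "ref", "alt", "variant_class")])
    all_chr <- unique(c(genes$chrom, elements$chrom, v$chrom))
    flank <- GenomicRanges::GRanges(
      factor(genes$chrom, all_chr),
      IRanges::IRanges(start = genes$start - window + 1L, end = genes$end + window))
    egr <- GenomicRanges::GRanges(
      factor(elements$chrom, all_chr),
      IRanges::IRanges(start = elements$start + 1L, end = elements$end))
    vgr <- GenomicRanges::GRanges(
      factor(v$chrom, all_chr),
      IRanges::IRanges(start = v$pos + 1L, width = 1L))
    eg <- GenomicRanges::findOverlaps(egr, flank)
    ve <- GenomicRanges::findOverlaps(vgr, egr)
    if (length(eg) && length(ve)) {
      pairs <- merge(
        data.frame(elem = S4Vectors::queryHits(eg),
                   gene = S4Vectors::subjectHits(eg)),
        data.frame(var = S4Vectors::queryHits(ve),
                   elem = S4Vectors::subjectHits(ve)),
        by = "elem")
      pairs$kind <- elements$kind[pairs$elem]
      # one count per distinct (gene, variant, element kind)
      pairs <- unique(pairs[, c("gene", "var", "kind")])
      pairs$class <- v$variant_class[pairs$var]
      feat <- paste0(pairs$kind, ifelse(pairs$class == "SNP",
                                        "_snp", "_indel"))
      tab <- table(factor(pairs$gene, seq_len(nrow(genes))),
                   factor(feat, features))
      m[] <- as.integer(tab)
    }
  }
  qtg_features(m + 0, kinds = "count")
}

#' Fraction of accessions lacking each gene
#'
#' @param pav integer matrix of 1 (present) / 0 (absent), genes x
#'   accessions, as from [read_pav_matrix()].
#' @return `qtg_features` fragment with the single fraction feature
#'   `percent_absence`.
#' @export
compute_percent_absence <- function(pav) {
  if (!ncol(pav)) stop("presence/absence matrix needs >= 1 accession")
  if (!all(pav %in% c(0L, 1L))) stop("presence/absence matrix must be 0/1")
  m <- matrix(rowMeans(pav == 0L), ncol = 1,
              dimnames = list(rownames(pav), "percent_absence"))
  qtg_features(m, kinds = "fraction")
}

#' Default GO-slim to function-feature mapping
#'
#' Transporter activity and DNA-binding transcription factor activity are
#' the two molecular-function slims encoded as model features by default.
#' @return Named character vector: slim GO ID -> feature name.
#' @export
default_go_schema <- function() {
  c("GO:0005215" = "is_transporter",
    "GO:0003700" = "is_transcription_factor")
}

#' Binary function features from GO annotations via a GO-slim mapping
#'
#' A feature is 1 for a gene iff any of its annotated GO terms is the
#' schema's slim term itself or has it among its slim ancestors.  GO IDs
#' absent from the slim mapping are treated as unmapped and counted in the
#' `"unmapped_terms"` attribute.
#'
#' @param annotations named list gene -> character vector of GO IDs, as
#'   from [read_go_annotations()].
#' @param slim_map named list GO ID -> character vector of slim ancestors,
#'   as from [read_slim_map()].
#' @param genes data.frame of gene models (only `gene_id` used).
#' @param go_schema named character vector slim ID -> feature name.
#' @return `qtg_features` fragment of binary function features.
#' @export
aggregate_go_features <- function(annotations, slim_map, genes,
                                  go_schema = default_go_schema()) {
  m <- matrix(0, nrow = nrow(genes), ncol = length(go_schema),
              dimnames = list(genes$gene_id, unname(go_schema)))
  unmapped <- 0L
  for (g in intersect(names(annotations), genes$gene_id)) {
    for (term in annotations[[g]]) {
      ancestors <- c(term, slim_map[[term]])
      if (is.null(slim_map[[term]]) && !(term %in% names(go_schema)))
        unmapped <- unmapped + 1L
      hits <- intersect(ancestors, names(go_schema))
      if (length(hits)) m[g, go_schema[hits]] <- 1
    }
  }
  out <- qtg_features(m, kinds = "binary")
  attr(out, "unmapped_terms") <- unmapped
  out
}

#' Paralog copy number from orthogroup membership
#'
#' A gene's paralog copy number is the number of members its orthogroup has
#' in the given species.  Genes belonging to no orthogroup are singletons
#' and get copy number 1.
#'
#' @param orthogroups data.frame as from [read_orthogroups()].
#' @param genes data.frame of gene models (only `gene_id` used).
#' @param species the target species label used in `orthogroups$species`.
#' @return `qtg_features` fragment with the count feature
#'   `paralog_copy_number`.
#' @export
attach_paralog_counts <- function(orthogroups, genes, species) {
  counts <- rep(1L, nrow(genes))
  names(counts) <- genes$gene_id
  og <- orthogroups[orthogroups$species == species, , drop = FALSE]
  if (nrow(og)) {
    size <- table(og$orthogroup)
    hit <- og$gene_id %in% genes$gene_id
    counts[og$gene_id[hit]] <- as.integer(size[og$orthogroup[hit]])
  }
  m <- matrix(as.numeric(counts), ncol = 1,
              dimnames = list(genes$gene_id, "paralog_copy_number"))
  qtg_features(m, kinds = "count")
}

#' Binary metabolic-domain flags from a precomputed gene-to-domain table
#'
#' Metabolic-domain membership is a data dependency (a lookup against a
#' metabolic-network database), consumed here as a two-column table.
#'
#' @param domains data.frame with columns `gene_id`, `domain`.
#' @param genes data.frame of gene models (only `gene_id` used).
#' @return `qtg_features` fragment with one binary feature
#'   `domain_<name>` per distinct domain.
#' @export
encode_metabolic_domains <- function(domains, genes) {
  doms <- sort(unique(domains$domain))
  if (!length(doms)) stop("no metabolic domains in table")
  m <- matrix(0, nrow = nrow(genes), ncol = length(doms),
              dimnames = list(genes$gene_id, paste0("domain_", doms)))
  keep <- domains$gene_id %in% genes$gene_id
  m[cbind(domains$gene_id[keep], paste0("domain_", domains$domain[keep]))] <- 1
  qtg_features(m, kinds = "binary")
}

#' Build the full per-gene feature table from input files
#'
#' Orchestrates the individual extractors over the standard file formats
#' and merges the fragments over the GFF3 gene universe.  Any of the input
#' paths other than the GFF3 may be `NULL`, in which case that feature
#' block is omitted.
#'
#' @param gff GFF3 gene models (defines the gene universe).
#' @param vcf effect-annotated VCF; feeds both the binary polymorphism
#'   features and the conserved-element counts.
#' @param elements BED-like conserved-element file (CE and TFBS rows).
#' @param pav presence/absence TSV.
#' @param go,slim GO annotation and GO-slim mapping TSVs (both required for
#'   the function features).
#' @param orthogroups orthogroup membership TSV.
#' @param species target species label for the paralog counts.
#' @param domains optional gene-to-metabolic-domain TSV (columns
#'   `gene_id`, `domain`).
#' @param window flank in bp for conserved-element assignment.
#' @param schema effect schema (list or path to YAML).
#' @return A `qtg_features` table over all genes in `gff`.
#' @export
build_feature_table <- function(gff, vcf = NULL, elements = NULL, pav = NULL,
                                go = NULL, slim = NULL, orthogroups = NULL,
                                species = NULL, domains = NULL,
                                window = 1000L,
                                schema = default_effect_schema()) {
  if (is.character(schema)) schema <- read_effect_schema(schema)
  genes <- read_gene_models(gff)
  frags <- list()
  if (!is.null(vcf)) {
    variants <- read_annotated_variants(vcf)
    frags <- c(frags, list(encode_variant_features(variants, genes, schema)))
    if (!is.null(elements))
      frags <- c(frags, list(count_cns_polymorphisms(
        variants, read_conserved_elements(elements), genes, window = window)))
  }
  if (!is.null(pav))
    frags <- c(frags, list(compute_percent_absence(read_pav_matrix(pav))))
  if (!is.null(go) && !is.null(slim))
    frags <- c(frags, list(aggregate_go_features(
      read_go_annotations(go), read_slim_map(slim), genes)))
  if (!is.null(domains))
    frags <- c(frags, list(encode_metabolic_domains(read_tsv(domains,
      required = c("gene_id", "domain")), genes)))
  if (!is.null(orthogroups)) {
    if (is.null(species))
      stop("'species' is required with 'orthogroups'")
    frags <- c(frags, list(attach_paralog_counts(
      read_orthogroups(orthogroups), genes, species)))
  }
  if (!length(frags)) stop("no feature inputs given")
  merge_feature_fragments(frags, genes$gene_id)
}
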