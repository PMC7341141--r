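#' Read and write tab-separated tables with provenance comments
#'
#' The interchange dialect used throughout the package: tab-delimited text
#' with a header row, where lines starting with `#` carry provenance
#' (package version, seed, configuration) and are skipped on read.  Tabs are
#' used rather than commas because plant gene IDs routinely contain dots
#' (e.g. `Sobic.001G394400`).
#'
#' @param path file path.
#' @param required character vector of column names that must be present
#'   (order-insensitive); missing columns raise an error naming them.
#' @return `read_tsv()` returns a data.frame with character columns
#'   converted as by `type.convert`; `write_tsv()` returns `path` invisibly.
#' @export
read_tsv <- function(path, required = NULL) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!is.null(required)) {
    missing <- setdiff(required, names(df))
    if (length(missing))
      stop("file ", path, " lacks required column(s): ",
           paste(missing, collapse = ", "))
  }
  df
}

#' @rdname read_tsv
#' @param x data.frame to write.
#' @param provenance optional character vector of provenance lines, written
#'   as `#`-prefixed comments above the header together with the package
#'   version.
#' @export
write_tsv <- function(x, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  header <- c(paste0("# qtgrank ",
                     as.character(utils::packageVersion("qtgrank"))),
              if (length(provenance)) paste0("# ", provenance))
  writeLines(header, con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Extracts `gene` records and converts the GFF3 1-based inclusive
#' coordinates to the package's internal 0-based half-open convention.
#'
#' @param path GFF3 file path.
#' @param feature_type GFF3 `type` value identifying gene records.
#' @param id_attribute attribute holding the gene identifier.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open) and `strand`.
#' @export
read_gene_models <- function(path, feature_type = "gene",
                             id_attribute = "ID") {
  g <- rtracklayer::readGFF(path)
  g <- g[g$type == feature_type, , drop = FALSE]
  if (!nrow(g)) stop("no '", feature_type, "' records in ", path)
  ids <- as.character(g[[id_attribute]])
  if (anyNA(ids)) stop("gene record without '", id_attribute, "' in ", path)
  out <- data.frame(gene_id = ids,
                    chrom = as.character(g$seqid),
                    start = as.integer(g$start) - 1L,
                    end = as.integer(g$end),
                    strand = as.character(g$strand),
                    stringsAsFactors = FALSE)
  if (any(out$start >= out$end))
    stop("gene with start >= end in ", path)
  if (anyDuplicated(out$gene_id))
    stop("duplicate gene IDs in ", path)
  out
}

#' Read effect-annotated variants from VCF
#'
#' Parses SnpEff-style `ANN=` INFO annotations (subfields
#' `Allele|Annotation|Impact|Gene_Name|Gene_ID|...`, multiple annotations
#' comma-separated, compound effects joined by `&`) and a SIFT-style
#' pathogenicity INFO key.  Multi-allelic records are split per alternate
#' allele, and the variant class is derived from the allele lengths: equal
#' length 1 is a SNP, anything else an indel.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param ann_key INFO key carrying the effect annotation.
#' @param sift_key INFO key carrying the SIFT-style call; a value starting
#'   with `"deleterious"` sets the deleterious flag, one starting with
#'   `"tolerated"` clears it, absence leaves it `NA`.
#' @return data.frame with one row per (alternate allele, annotation):
#'   `chrom`, `pos` (0-based), `ref`, `alt`, `variant_class`
#'   (`"SNP"`/`"indel"`), `gene_id` (`NA` when the annotation names no
#'   gene), `effects` (`&`-joined effect terms) and `deleterious`
#'   (logical, `NA` when no call).
#' @export
read_annotated_variants <- function(path, ann_key = "ANN",
                                    sift_key = "SIFT") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  info <- vcfR::getINFO(v)
  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    ref <- fix[i, "REF"]
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    ann <- info_field(info[i], ann_key)
    sift <- info_field(info[i], sift_key)
    del <- if (is.na(sift)) NA else startsWith(tolower(sift), "deleterious")
    anns <- if (is.na(ann)) character(0) else
      strsplit(ann, ",", fixed = TRUE)[[1]]
    rows[[i]] <- variant_rows(fix[i, "CHROM"],
                              as.integer(fix[i, "POS"]) - 1L,
                              ref, alts, anns, del)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# expand one VCF record into per-allele, per-annotation rows
variant_rows <- function(chrom, pos0, ref, alts, anns, deleterious) {
  ann_allele <- ann_effect <- ann_gene <- character(length(anns))
  for (k in seq_along(anns)) {
    f <- strsplit(anns[k], "|", fixed = TRUE)[[1]]
    ann_allele[k] <- f[1]
    ann_effect[k] <- if (length(f) >= 2) f[2] else ""
    ann_gene[k] <- if (length(f) >= 5 && nzchar(f[5])) f[5] else NA_character_
  }
  out <- lapply(alts, function(alt) {
    cls <- if (nchar(ref) == 1L && nchar(alt) == 1L) "SNP" else "indel"
    hit <- which(ann_allele == alt)
    if (!length(hit))
      return(data.frame(chrom = chrom, pos = pos0, ref = ref, alt = alt,
                        variant_class = cls, gene_id = NA_character_,
                        effects = NA_character_, deleterious = deleterious,
                        stringsAsFactors = FALSE))
    data.frame(chrom = chrom, pos = pos0, ref = ref, alt = alt,
               variant_class = cls, gene_id = ann_gene[hit],
               effects = ann_effect[hit], deleterious = deleterious,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

info_field <- function(info, key) {
  if (is.na(info)) return(NA_character_)
  parts <- strsplit(info, ";", fixed = TRUE)[[1]]
  hit <- grep(paste0("^", key, "="), parts, value = TRUE)
  if (!length(hit)) return(NA_character_)
  sub(paste0("^", key, "="), "", hit[1])
}

#' Read conserved-element intervals
#'
#' BED-like tab-separated file with columns `chrom`, `start`, `end`
#' (0-based half-open, as in BED), `kind` (`CE` or `TFBS`) and optional
#' `element_id`.
#'
#' @param path file path.
#' @return data.frame with columns `element_id`, `chrom`, `start`, `end`,
#'   `kind`.  Elements with `start >= end` are rejected.
#' @export
read_conserved_elements <- function(path) {
  df <- read_tsv(path, required = c("chrom", "start", "end", "kind"))
  if (is.null(df$element_id))
    df$element_id <- paste0("elem", seq_len(nrow(df)))
  if (nrow(df) && any(df$start >= df$end))
    stop("conserved element with start >= end in ", path)
  bad <- setdiff(df$kind, c("CE", "TFBS"))
  if (length(bad))
    stop("unknown element kind in ", path, ": ", paste(bad, collapse = ", "))
  df[, c("element_id", "chrom", "start", "end", "kind")]
}

#' Read a gene presence/absence matrix
#'
#' Tab-separated with a `gene_id` column followed by one 0/1 column per
#' accession (1 = present, 0 = absent).
#'
#' @param path file path.
#' @return integer matrix, genes x accessions.
#' @export
read_pav_matrix <- function(path) {
  df <- read_tsv(path, required = "gene_id")
  acc <- setdiff(names(df), "gene_id")
  if (!length(acc)) stop("presence/absence file needs >= 1 accession column")
  m <- as.matrix(df[, acc, drop = FALSE])
  bad <- which(matrix(!(m %in% c(0, 1)), nrow(m)), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-binary presence/absence cell at gene ",
         df$gene_id[bad[1, 1]], ", accession ", acc[bad[1, 2]])
  storage.mode(m) <- "integer"
  rownames(m) <- df$gene_id
  m
}

#' Read GO annotations and a GO-slim mapping
#'
#' `read_go_annotations()` expects columns `gene_id`, `go_id`;
#' `read_slim_map()` expects columns `go_id`, `slim_id` (one row per
#' ancestor).
#'
#' @param path file path.
#' @return A named list: gene -> character vector of GO IDs, or
#'   GO ID -> character vector of slim ancestors.
#' @export
read_go_annotations <- function(path) {
  df <- read_tsv(path, required = c("gene_id", "go_id"))
  split(df$go_id, df$gene_id)
}

#' @rdname read_go_annotations
#' @export
read_slim_map <- function(path) {
  df <- read_tsv(path, required = c("go_id", "slim_id"))
  split(df$slim_id, df$go_id)
}

#' Read orthogroup membership
#'
#' OrthoFinder-style long table with columns `orthogroup`, `species`,
#' `gene_id`, one row per member.
#'
#' @param path file path.
#' @return data.frame with those three columns.
#' @export
read_orthogroups <- function(path) {
  df <- read_tsv(path, required = c("orthogroup", "species", "gene_id"))
  if (anyDuplicated(df$gene_id))
    stop("gene assigned to more than one orthogroup in ", path)
  df
}

#' Read curated causal genes and ortholog maps
#'
#' `read_causal_genes()`: columns `gene_id`, `species` and optionally
#' `trait`, `source`.  `read_ortholog_map()`: columns `causal_id`,
#' `causal_species`, `ortholog_id`, `ortholog_species`, `kind` with kind in
#' `fine_grained`, `group_member` or `collinear`.
#'
#' @param path file path.
#' @return data.frame of the listed columns.
#' @export
read_causal_genes <- function(path) {
  df <- read_tsv(path, required = c("gene_id", "species"))
  if (anyDuplicated(df[, c("gene_id", "species")]))
    stop("duplicate (gene_id, species) pair in ", path)
  df
}

#' @rdname read_causal_genes
#' @export
read_ortholog_map <- function(path) {
  df <- read_tsv(path, required = c("causal_id", "causal_species",
                                    "ortholog_id", "ortholog_species",
                                    "kind"))
  bad <- setdiff(df$kind, c("fine_grained", "group_member", "collinear"))
  if (length(bad))
    stop("unknown orthology kind in ", path, ": ",
         paste(bad, collapse = ", "))
  df
}

#' Read QTL definitions as gene lists
#'
#' Columns `qtl_id`, `trait`, `gene_ids` (comma-separated list of the
#' interval's genes) and optionally `causal_gene` (empty when unknown).
#'
#' @param path file path.
#' @return named list of QTL records, each a list with `qtl_id`, `trait`,
#'   `gene_ids` (character) and `causal_gene` (`NA` when unknown).
#' @export
read_qtls <- function(path) {
  df <- read_tsv(path, required = c("qtl_id", "trait", "gene_ids"))
  qtls <- lapply(seq_len(nrow(df)), function(i) {
    genes <- strsplit(df$gene_ids[i], ",", fixed = TRUE)[[1]]
    causal <- if (!is.null(df$causal_gene) && nzchar(df$causal_gene[i]))
      df$causal_gene[i] else NA_character_
    qtl_region(df$qtl_id[i], genes, causal_gene = causal,
               trait = df$trait[i])
  })
  names(qtls) <- df$qtl_id
  qtls
}

#' Write and read a feature table as TSV
#'
#' The table is written with a `gene_id` column followed by one column per
#' feature; the declared feature kinds go to a sidecar file
#' `<path>.kinds.tsv` so the typed table round-trips.
#'
#' @param x a `qtg_features` object.
#' @param path output TSV path.
#' @param provenance passed to [write_tsv()].
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns a `qtg_features` object.
#' @export
write_feature_table <- function(x, path, provenance = NULL) {
  df <- data.frame(gene_id = feature_genes(x), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path, provenance = provenance)
  write_tsv(data.frame(feature = names(x$kinds), kind = unname(x$kinds)),
            paste0(path, ".kinds.tsv"))
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read_tsv(path, required = "gene_id")
  kinds <- read_tsv(paste0(path, ".kinds.tsv"),
                    required = c("feature", "kind"))
  m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  rownames(m) <- df$gene_id
  qtg_features(m[, kinds$feature, drop = FALSE],
               kinds = stats::setNames(kinds$kind, kinds$feature)[colnames(m)])
}
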