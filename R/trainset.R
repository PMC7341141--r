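#' Select orthologs of one causal gene with fine-grained preference
#'
#' Given all ortholog-map entries for a single causal gene, returns the
#' target-species orthologs: if at least one pairwise (fine-grained)
#' orthology call exists for the target species, only those genes are used;
#' otherwise every ortholog-group member (or collinearity-mapped gene) in
#' the target species is used.
#'
#' @param entries data.frame of ortholog-map rows (columns `ortholog_id`,
#'   `ortholog_species`, `kind`) all belonging to one causal gene.
#' @param target_species species whose orthologs are wanted.
#' @return Character vector of target-species ortholog gene IDs (possibly
#'   empty).
#' @export
apply_fine_grained_preference <- function(entries, target_species) {
  e <- entries[entries$ortholog_species == target_species, , drop = FALSE]
  if (!nrow(e)) return(character(0))
  fg <- e$ortholog_id[e$kind == "fine_grained"]
  if (length(fg)) unique(fg) else unique(e$ortholog_id)
}

#' Assemble the positive training set for a target species
#'
#' Positives come from the species' own curated causal genes
#' (`known_only`), from target-species orthologs of causal genes curated in
#' *other* species (`orthologs_only`), or from both (`combined`).  Ortholog
#' selection applies the fine-grained preference per causal gene; under
#' `lineage_constraint = "same_lineage"` only causal genes from the same
#' lineage (monocot or eudicot) as the target species contribute orthologs,
#' and species missing from `lineage_table` fail closed.  A gene reachable
#' both as a known causal gene and as an ortholog keeps provenance
#' `known_causal`.  Exclusions (e.g. an external validation set) are
#' removed last.
#'
#' @param causal data.frame of curated causal genes as from
#'   [read_causal_genes()].
#' @param omap data.frame ortholog map as from [read_ortholog_map()].
#' @param target_species target species label.
#' @param mode one of `"known_only"`, `"orthologs_only"`, `"combined"`.
#' @param lineage_constraint `"none"` or `"same_lineage"`.
#' @param lineage_table named character vector species -> lineage
#'   (`"monocot"`/`"eudicot"`); required under `same_lineage`.
#' @param exclusions character vector of gene IDs never to emit.
#' @return data.frame with columns `gene_id` and `provenance`
#'   (`known_causal` or `ortholog`), deduplicated.
#' @export
expand_training_set <- function(causal, omap, target_species,
                                mode = c("combined", "known_only",
                                         "orthologs_only"),
                                lineage_constraint = c("none", "same_lineage"),
                                lineage_table = NULL,
                                exclusions = character(0)) {
  mode <- match.arg(mode)
  lineage_constraint <- match.arg(lineage_constraint)
  known <- unique(causal$gene_id[causal$species == target_species])

  orthologs <- character(0)
  if (mode != "known_only") {
    foreign <- causal[causal$species != target_species, , drop = FALSE]
    if (lineage_constraint == "same_lineage") {
      if (is.null(lineage_table) || !(target_species %in% names(lineage_table)))
        stop("target species '", target_species,
             "' missing from lineage table")
      target_lineage <- lineage_table[[target_species]]
      lin <- lineage_table[foreign$species]
      # species absent from the table fail closed
      foreign <- foreign[!is.na(lin) & lin == target_lineage, , drop = FALSE]
    }
    for (i in seq_len(nrow(foreign))) {
      entries <- omap[omap$causal_id == foreign$gene_id[i] &
                        omap$causal_species == foreign$species[i], ,
                      drop = FALSE]
      orthologs <- c(orthologs,
                     apply_fine_grained_preference(entries, target_species))
    }
    orthologs <- unique(orthologs)
  }

  pos <- switch(mode,
    known_only = data.frame(gene_id = known,
                            provenance = rep("known_causal", length(known)),
                            stringsAsFactors = FALSE),
    orthologs_only = data.frame(gene_id = orthologs,
                                provenance = rep("ortholog",
                                                 length(orthologs)),
                                stringsAsFactors = FALSE),
    combined = {
      ortho_new <- setdiff(orthologs, known)
      data.frame(gene_id = c(known, ortho_new),
                 provenance = c(rep("known_causal", length(known)),
                                rep("ortholog", length(ortho_new))),
                 stringsAsFactors = FALSE)
    })
  pos <- pos[!(pos$gene_id %in% exclusions), , drop = FALSE]
  rownames(pos) <- NULL
  if (!nrow(pos))
    stop("empty positive training set for '", target_species,
         "' under mode '", mode,
         "': check the species label, the ortholog map and the exclusions")
  pos
}

#' Remap positive gene IDs through an ID map
#'
#' Used when the ortholog resource annotates a close relative of the target
#' genome (e.g. a domesticated line) and collinear gene pairs supply the ID
#' conversion.  Unmapped IDs are dropped and reported in the `"dropped"`
#' attribute, not errors.
#'
#' @param positives data.frame with a `gene_id` column (e.g. from
#'   [expand_training_set()]).
#' @param id_map named character vector source ID -> target ID; must not
#'   map two sources to one target.
#' @return `positives` with mapped IDs, attribute `dropped` listing the
#'   unmapped source IDs.
#' @export
remap_gene_ids <- function(positives, id_map) {
  if (anyDuplicated(unname(id_map[!is.na(id_map)])))
    stop("id_map maps two source IDs to the same target ID")
  mapped <- id_map[positives$gene_id]
  keep <- !is.na(mapped)
  out <- positives[keep, , drop = FALSE]
  out$gene_id <- unname(mapped[keep])
  rownames(out) <- NULL
  attr(out, "dropped") <- positives$gene_id[!keep]
  out
}
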