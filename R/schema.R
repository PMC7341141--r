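#' Default effect-term to binary-feature schema
#'
#' Maps controlled-vocabulary variant effect terms (SnpEff-style) to the
#' binary polymorphism features of the model.  Each rule lists the effect
#' terms it matches and, where pathogenicity matters, whether a SIFT-style
#' deleterious call is required (`TRUE`), forbidden (`FALSE`) or ignored
#' (`NA`).  A missense variant with no SIFT-style call matches neither
#' nonsynonymous rule: pathogenicity is never imputed.
#'
#' The exact feature list used by the original per-species models is spread
#' across upstream annotation tools; this default is a documented
#' reconstruction covering the standard SnpEff effect classes and can be
#' replaced with a YAML file via [read_effect_schema()].
#'
#' @return Named list of rules; each rule has `terms` (character) and
#'   `deleterious` (logical scalar, possibly `NA`).
#' @export
default_effect_schema <- function() {
  list(
    is_nonsyn_deleterious = list(terms = "missense_variant",
                                 deleterious = TRUE),
    is_nonsyn_tolerated   = list(terms = "missense_variant",
                                 deleterious = FALSE),
    is_synonymous  = list(terms = "synonymous_variant", deleterious = NA),
    is_frameshift  = list(terms = "frameshift_variant", deleterious = NA),
    is_stop_gained = list(terms = "stop_gained", deleterious = NA),
    is_stop_lost   = list(terms = "stop_lost", deleterious = NA),
    is_splice      = list(terms = c("splice_region_variant",
                                    "splice_donor_variant",
                                    "splice_acceptor_variant"),
                          deleterious = NA),
    is_utr         = list(terms = c("5_prime_UTR_variant",
                                    "3_prime_UTR_variant"),
                          deleterious = NA),
    is_intron      = list(terms = "intron_variant", deleterious = NA),
    is_upstream    = list(terms = "upstream_gene_variant", deleterious = NA),
    is_downstream  = list(terms = "downstream_gene_variant", deleterious = NA)
  )
}

#' Read an effect schema from YAML
#'
#' The file maps feature names to `terms` (a list of effect strings) and an
#' optional `deleterious` flag, mirroring [default_effect_schema()].
#'
#' @param path YAML file path.
#' @return Schema list as for [default_effect_schema()].
#' @export
read_effect_schema <- function(path) {
  raw <- yaml::read_yaml(path)
  schema <- lapply(raw, function(r) {
    if (is.null(r$terms)) stop("schema rule without 'terms' in ", path)
    list(terms = as.character(r$terms),
         deleterious = if (is.null(r$deleterious)) NA else as.logical(r$deleterious))
  })
  validate_effect_schema(schema)
  schema
}

# each (term, deleterious-status) category must map to at most one feature
validate_effect_schema <- function(schema) {
  keys <- unlist(lapply(schema, function(r)
    paste(r$terms, r$deleterious, sep = "/")))
  if (anyDuplicated(keys))
    stop("effect category mapped by more than one schema rule: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  invisible(schema)
}

#' Write an effect schema to YAML
#' @param schema schema list as from [default_effect_schema()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_effect_schema <- function(schema, path) {
  yaml::write_yaml(schema, path)
  invisible(path)
}
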