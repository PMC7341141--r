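#' Run the full prioritization pipeline from input files
#'
#' Orchestrates feature extraction, training-set assembly, ensemble
#' fitting, QTL ranking and (when the QTLs carry known causal genes)
#' external validation.  Every output table carries a provenance comment
#' block with the package version, the seed and a configuration digest, so
#' a rerun with an identical configuration is byte-identical apart from
#' nothing: no timestamps are written.
#'
#' @param config named list or path to a YAML file with entries:
#'   `gff` (required), `vcf`, `elements`, `pav`, `go`, `slim`,
#'   `orthogroups`, `domains` (feature inputs); `species`;
#'   `causal` (curated causal-gene TSV), `ortholog_map` (optional),
#'   `mode`, `exclusions` (optional gene-ID file, one per line);
#'   `qtls` (QTL definition TSV); `out_dir`; `seed`; and optional model
#'   settings `n_trees`, `n_iter`, `neg_pos_ratio`, `window`, `cutoffs`.
#' @return Invisibly, a list with the fitted `model`, the `scores`, the
#'   per-QTL `ranks`, the `validation` summary (or `NULL`) and the output
#'   file paths.
#' @export
qtg_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  req <- c("gff", "causal", "qtls", "out_dir", "species")
  missing <- setdiff(req, names(config))
  if (length(missing))
    stop("pipeline config lacks: ", paste(missing, collapse = ", "))
  for (f in intersect(c("gff", "vcf", "elements", "pav", "go", "slim",
                        "orthogroups", "domains", "causal", "ortholog_map",
                        "qtls", "exclusions"), names(config)))
    if (!file.exists(config[[f]]))
      stop("input path does not exist: ", config[[f]], " (", f, ")")
  cfg <- function(nm, dflt) if (is.null(config[[nm]])) dflt else config[[nm]]
  seed <- cfg("seed", 1L)
  prov <- c(paste0("seed: ", seed),
            paste0("config: ", config_digest(config)))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$out_dir, name)

  features <- build_feature_table(
    gff = config$gff, vcf = config$vcf, elements = config$elements,
    pav = config$pav, go = config$go, slim = config$slim,
    orthogroups = config$orthogroups, species = config$species,
    domains = config$domains, window = cfg("window", 1000L),
    schema = if (is.null(config$schema)) default_effect_schema()
             else config$schema)
  write_feature_table(features, out("features.tsv"), provenance = prov)

  causal <- read_causal_genes(config$causal)
  omap <- if (!is.null(config$ortholog_map))
    read_ortholog_map(config$ortholog_map)
  else data.frame(causal_id = character(0), causal_species = character(0),
                  ortholog_id = character(0),
                  ortholog_species = character(0), kind = character(0))
  exclusions <- if (!is.null(config$exclusions))
    readLines(config$exclusions) else character(0)
  positives <- expand_training_set(
    causal, omap, target_species = config$species,
    mode = cfg("mode", "combined"), exclusions = exclusions)
  write_tsv(positives, out("trainset.tsv"), provenance = prov)

  model <- qtg_fit(features, positives,
                   n_trees = cfg("n_trees", 200),
                   neg_pos_ratio = cfg("neg_pos_ratio", 1),
                   n_iter = cfg("n_iter", 50), seed = seed)
  scores <- predict(model)
  write_tsv(data.frame(gene_id = names(scores), score = unname(scores)),
            out("scores.tsv"), provenance = prov)

  qtls <- read_qtls(config$qtls)
  ranks <- lapply(qtls, function(q) rank_qtl(scores, q))
  write_tsv(do.call(rbind, lapply(ranks, function(r)
    data.frame(qtl_id = attr(r, "qtl_id"), as.data.frame(r)))),
    out("ranks.tsv"), provenance = prov)

  validation <- NULL
  with_causal <- Filter(function(q) !is.na(q$causal_gene), qtls)
  if (length(with_causal)) {
    validation <- qtg_validate(scores, with_causal,
                               cutoffs = cfg("cutoffs", c(5, 10, 20)))
    report <- data.frame(cutoff = validation$cutoffs,
                         recall = unname(validation$recall),
                         avg_precision = unname(validation$precision),
                         background = unname(validation$background))
    write_tsv(report, out("validation.tsv"), provenance = prov)
    write_tsv(validation$detail, out("validation_detail.tsv"),
              provenance = prov)
  }
  invisible(list(model = model, scores = scores, ranks = ranks,
                 validation = validation,
                 paths = list.files(config$out_dir, full.names = TRUE)))
}

# order-insensitive digest of the analysis configuration, for provenance
# lines; the output location is not part of the analysis
config_digest <- function(config) {
  config <- config[setdiff(names(config), "out_dir")]
  config <- config[order(names(config))]
  txt <- paste(names(config),
               vapply(config, function(v) paste(format(v), collapse = ","),
                      ""),
               sep = "=", collapse = ";")
  codes <- utf8ToInt(txt)
  sprintf("%08x",
          sum(codes * (seq_along(codes) %% 97 + 1)) %% 2147483647)
}
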