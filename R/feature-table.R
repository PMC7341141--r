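#' Per-gene feature table
#'
#' The container consumed by [qtg_fit()]: a genes x features numeric matrix
#' plus a declared kind for every feature.  Kinds are enforced on
#' construction: `binary` features must lie in \{0, 1\}, `count` features must
#' be non-negative integers, `fraction` features must lie in \[0, 1\].
#'
#' @param values numeric matrix, one row per gene; rownames are gene IDs and
#'   colnames are feature names, both unique.
#' @param kinds character vector of `"binary"`, `"count"` or `"fraction"`,
#'   one per column (recycled if length 1).
#' @return An object of class `qtg_features`.
#' @examples
#' m <- cbind(is_nonsyn_deleterious = c(1, 0), CE_snp = c(3, 0))
#' rownames(m) <- c("g1", "g2")
#' qtg_features(m, kinds = c("binary", "count"))
#' @export
qtg_features <- function(values, kinds) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' needs gene IDs as rownames and feature names as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate feature names: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (length(kinds) == 1L) kinds <- rep(kinds, ncol(values))
  if (length(kinds) != ncol(values))
    stop("'kinds' must have one entry per feature column")
  bad <- setdiff(kinds, c("binary", "count", "fraction"))
  if (length(bad)) stop("unknown feature kind: ", paste(bad, collapse = ", "))
  names(kinds) <- colnames(values)
  for (j in seq_len(ncol(values))) {
    v <- values[, j]
    if (anyNA(v)) stop("NA in feature ", colnames(values)[j])
    ok <- switch(kinds[j],
      binary   = all(v %in% c(0, 1)),
      count    = all(v >= 0 & v == round(v)),
      fraction = all(v >= 0 & v <= 1))
    if (!ok)
      stop("feature ", colnames(values)[j], " violates its declared kind '",
           kinds[j], "'")
  }
  structure(list(values = values, kinds = kinds), class = "qtg_features")
}

#' @export
print.qtg_features <- function(x, ...) {
  cat("Per-gene feature table:", nrow(x$values), "genes x",
      ncol(x$values), "features\n")
  tab <- table(factor(x$kinds, levels = c("binary", "count", "fraction")))
  cat("  kinds:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  features:", paste(utils::head(colnames(x$values), 8), collapse = ", "),
      if (ncol(x$values) > 8) "...", "\n")
  invisible(x)
}

#' @export
as.matrix.qtg_features <- function(x, ...) x$values

#' @export
dim.qtg_features <- function(x) dim(x$values)

#' Gene IDs and feature names of a feature table
#' @param x a `qtg_features` object.
#' @return Character vector of gene IDs (`feature_genes`) or feature names
#'   (`feature_names`).
#' @export
feature_genes <- function(x) rownames(x$values)

#' @rdname feature_genes
#' @export
feature_names <- function(x) colnames(x$values)

#' Merge feature-table fragments over a gene universe
#'
#' Column-binds fragments produced by the individual extractors into one
#' table covering every gene in `universe`.  A gene missing from a fragment
#' receives that fragment's imputation default: 0 for binary, count and
#' fraction features, 1 for `paralog_copy_number` (every gene has at least
#' itself as a paralog).
#'
#' @param fragments list of `qtg_features` fragments with pairwise-disjoint
#'   feature names; every fragment's genes must be contained in `universe`.
#' @param universe character vector of gene IDs for the merged table.
#' @return A `qtg_features` table with `length(universe)` rows, in
#'   `universe` order.
#' @export
merge_feature_fragments <- function(fragments, universe) {
  if (anyDuplicated(universe)) stop("duplicate gene IDs in universe")
  nm <- unlist(lapply(fragments, feature_names))
  if (anyDuplicated(nm))
    stop("duplicate feature name across fragments: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  cols <- vector("list", length(fragments))
  kinds <- character(0)
  for (i in seq_along(fragments)) {
    fr <- fragments[[i]]
    extra <- setdiff(feature_genes(fr), universe)
    if (length(extra))
      stop("fragment genes outside universe: ", paste(extra, collapse = ", "))
    m <- matrix(0, nrow = length(universe), ncol = ncol(fr$values),
                dimnames = list(universe, colnames(fr$values)))
    if ("paralog_copy_number" %in% colnames(m))
      m[, "paralog_copy_number"] <- 1
    m[feature_genes(fr), ] <- fr$values
    cols[[i]] <- m
    kinds <- c(kinds, fr$kinds)
  }
  qtg_features(do.call(cbind, cols), kinds = kinds)
}
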