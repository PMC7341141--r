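#' Tie-aware area under the ROC curve
#'
#' Rank-based AUC: the probability that a randomly chosen positive scores
#' above a randomly chosen negative, counting ties as one half.  Equivalent
#' to trapezoidal integration of the ROC curve with tied scores collapsed.
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels logical (or 0/1) vector, `TRUE` for positives.
#' @return AUC in \[0, 1\].
#' @export
auc_roc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("AUC needs both positives and negatives")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# deterministic stream of sub-seeds from one top-level seed
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Sample a negative training set from the genome
#'
#' Uniform sample without replacement from the genome genes not in the
#' positive set, of size `round(neg_pos_ratio * length(positives))`.
#'
#' @param genome_genes character vector of all candidate gene IDs.
#' @param positives character vector of positive gene IDs.
#' @param neg_pos_ratio negatives drawn per positive.
#' @param seed integer seed making the draw reproducible.
#' @return Character vector of negative gene IDs, disjoint from
#'   `positives`.
#' @export
sample_negatives <- function(genome_genes, positives, neg_pos_ratio = 1,
                             seed = 1L) {
  pool <- setdiff(genome_genes, positives)
  n <- round(neg_pos_ratio * length(unique(positives)))
  if (length(pool) < n)
    stop("negative pool too small: need ", n, ", have ", length(pool))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample(pool, n)
}

#' Fit the negative-resampling random-forest ensemble
#'
#' The class imbalance between a handful of causal genes and a whole
#' genome is handled by resampling: each of `n_iter` iterations trains one
#' random forest on all positives plus an independently drawn random
#' negative set (`neg_pos_ratio` negatives per positive).  A gene's
#' ensemble score is the fraction of iterations whose forest classifies it
#' as causal, so genes that survive many different negative backgrounds
#' rise to the top.
#'
#' @param features `qtg_features` table (the model matrix).
#' @param positives character vector of positive gene IDs (or a data.frame
#'   with a `gene_id` column as from [expand_training_set()]).
#' @param n_trees trees per forest.
#' @param mtry features tried at each split; default `floor(sqrt(p))`.
#' @param min_node minimum terminal node size (the forest's stopping
#'   granularity; 1 grows trees fully).
#' @param neg_pos_ratio negatives sampled per positive in each iteration.
#' @param n_iter ensemble iterations (independent negative redraws).
#' @param seed top-level seed; per-iteration seeds are derived from it
#'   deterministically, so refitting with the same seed is reproducible.
#' @param aggregate `"vote"` scores a gene by the fraction of forests whose
#'   majority vote is causal; `"prob"` averages the forests' causal-class
#'   probabilities.
#' @return An object of class `qtg_model` with `predict`, `print`,
#'   `summary` and `plot` methods.
#' @seealso [qtg_cv()] for cross-validation, [qtg_importance()] for
#'   leave-one-out feature importance, [rank_qtl()] for ranking the genes
#'   of a QTL interval with the fitted model.
#' @examples
#' sim <- simulate_species(fixture_spec(n_genes = 300, seed = 7))
#' fit <- qtg_fit(sim$features, sim$causal, n_iter = 10, n_trees = 50)
#' head(predict(fit))
#' @export
qtg_fit <- function(features, positives, n_trees = 200, mtry = NULL,
                    min_node = 1, neg_pos_ratio = 1, n_iter = 50,
                    seed = 1L, aggregate = c("vote", "prob")) {
  aggregate <- match.arg(aggregate)
  if (is.data.frame(positives)) positives <- positives$gene_id
  positives <- unique(positives)
  x <- as.matrix(features)
  missing <- setdiff(positives, rownames(x))
  if (length(missing))
    stop("positives absent from the feature table: ",
         paste(missing, collapse = ", "))
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  seeds <- derive_seeds(seed, 2L * n_iter)
  forests <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    negs <- sample_negatives(rownames(x), positives, neg_pos_ratio,
                             seed = seeds[i])
    train <- rbind(x[positives, , drop = FALSE], x[negs, , drop = FALSE])
    y <- factor(rep(c("causal", "background"),
                    c(length(positives), length(negs))),
                levels = c("background", "causal"))
    set.seed(seeds[n_iter + i])
    forests[[i]] <- randomForest::randomForest(
      train, y, ntree = n_trees, mtry = mtry, nodesize = min_node)
  }
  structure(list(forests = forests,
                 feature_names = colnames(x),
                 positives = positives,
                 features = features,
                 config = list(n_trees = n_trees, mtry = mtry,
                               min_node = min_node,
                               neg_pos_ratio = neg_pos_ratio,
                               n_iter = n_iter, seed = seed,
                               aggregate = aggregate)),
            class = "qtg_model")
}

#' Score genes with a fitted ensemble
#'
#' @param object a `qtg_model`.
#' @param features `qtg_features` table to score; defaults to the training
#'   table.  Its columns must contain the model's features (order is
#'   realigned by name).
#' @param genes gene IDs to score; default all rows of `features`.
#' @param ... ignored.
#' @return Named numeric vector of ensemble scores in \[0, 1\].
#' @export
predict.qtg_model <- function(object, features = object$features,
                              genes = NULL, ...) {
  x <- as.matrix(features)
  missing <- setdiff(object$feature_names, colnames(x))
  if (length(missing))
    stop("feature table lacks model feature(s): ",
         paste(missing, collapse = ", "))
  x <- x[, object$feature_names, drop = FALSE]
  if (!is.null(genes)) {
    unknown <- setdiff(genes, rownames(x))
    if (length(unknown))
      stop("unknown gene(s): ", paste(unknown, collapse = ", "))
    x <- x[genes, , drop = FALSE]
  }
  acc <- numeric(nrow(x))
  for (f in object$forests) {
    if (object$config$aggregate == "vote") {
      acc <- acc + (predict(f, x, type = "response") == "causal")
    } else {
      acc <- acc + predict(f, x, type = "prob")[, "causal"]
    }
  }
  stats::setNames(acc / length(object$forests), rownames(x))
}

#' @export
print.qtg_model <- function(x, ...) {
  cfg <- x$config
  cat("Negative-resampling random-forest ensemble\n")
  cat(sprintf("  %d iterations x %d trees; %d positives, %.3g negatives per positive\n",
              cfg$n_iter, cfg$n_trees, length(x$positives),
              cfg$neg_pos_ratio))
  cat(sprintf("  %d features; score = %s; seed %d\n",
              length(x$feature_names),
              if (cfg$aggregate == "vote") "ensemble vote fraction"
              else "mean causal probability", cfg$seed))
  invisible(x)
}

#' @export
summary.qtg_model <- function(object, ...) {
  print(object)
  sc <- predict(object)
  cat("Training-table score distribution:\n")
  print(summary(sc))
  cat("Mean score, positives:  ",
      round(mean(sc[object$positives]), 3), "\n")
  cat("Mean score, background: ",
      round(mean(sc[setdiff(names(sc), object$positives)]), 3), "\n")
  invisible(object)
}

#' Plot ensemble score distributions for positives and background
#'
#' @param x a `qtg_model`.
#' @param ... passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.qtg_model <- function(x, ...) {
  sc <- predict(x)
  pos <- sc[x$positives]
  neg <- sc[setdiff(names(sc), x$positives)]
  br <- seq(0, 1, by = 0.05)
  graphics::hist(neg, breaks = br, col = "grey80", freq = FALSE,
                 main = "Ensemble scores", xlab = "score", ...)
  graphics::hist(pos, breaks = br, col = "#d9544d80", freq = FALSE,
                 add = TRUE)
  graphics::legend("topright", fill = c("grey80", "#d9544d80"),
                   legend = c("background", "positives"), bty = "n")
  invisible(x)
}

# stratified fold assignment: every fold keeps the positive:negative ratio
stratified_folds <- function(is_pos, n_folds) {
  fold <- integer(length(is_pos))
  fold[is_pos]  <- sample(rep_len(seq_len(n_folds), sum(is_pos)))
  fold[!is_pos] <- sample(rep_len(seq_len(n_folds), sum(!is_pos)))
  fold
}

#' Repeated stratified cross-validation of the ensemble classifier
#'
#' Each repeat draws a fresh random negative set, splits positives and
#' negatives into stratified folds, trains one forest per training split
#' and pools the held-out causal-class probabilities into one AUC-ROC per
#' repeat.  Precision, recall and F1 are computed at a causal-probability
#' threshold of 0.5, averaged over repeats.
#'
#' @inheritParams qtg_fit
#' @param n_folds folds per repeat (positives must number at least
#'   `n_folds` so that every fold holds a positive).
#' @param n_repeats independent repeats, each with its own negative draw.
#' @return An object of class `qtg_cv`: list with `auc` (length
#'   `n_repeats`), `mean`, `sd`, `precision`, `recall`, `f1` and the
#'   configuration.
#' @export
qtg_cv <- function(features, positives, n_folds = 5, n_repeats = 50,
                   n_trees = 200, mtry = NULL, min_node = 1,
                   neg_pos_ratio = 1, seed = 1L) {
  if (is.data.frame(positives)) positives <- positives$gene_id
  positives <- unique(positives)
  x <- as.matrix(features)
  if (length(positives) < n_folds)
    stop("need at least ", n_folds, " positives for ", n_folds,
         "-fold cross-validation")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  seeds <- derive_seeds(seed, n_repeats)
  auc <- prec <- rec <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    negs <- sample_negatives(rownames(x), positives, neg_pos_ratio,
                             seed = seeds[r])
    ids <- c(positives, negs)
    is_pos <- rep(c(TRUE, FALSE), c(length(positives), length(negs)))
    set.seed(seeds[r])
    fold <- stratified_folds(is_pos, n_folds)
    prob <- numeric(length(ids))
    for (k in seq_len(n_folds)) {
      tr <- fold != k
      y <- factor(ifelse(is_pos[tr], "causal", "background"),
                  levels = c("background", "causal"))
      f <- randomForest::randomForest(x[ids[tr], , drop = FALSE], y,
                                      ntree = n_trees, mtry = mtry,
                                      nodesize = min_node)
      prob[!tr] <- predict(f, x[ids[!tr], , drop = FALSE],
                           type = "prob")[, "causal"]
    }
    auc[r] <- auc_roc(prob, is_pos)
    called <- prob >= 0.5
    tp <- sum(called & is_pos)
    prec[r] <- if (any(called)) tp / sum(called) else 0
    rec[r] <- tp / sum(is_pos)
  }
  precision <- mean(prec); recall <- mean(rec)
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(list(auc = auc, mean = mean(auc), sd = stats::sd(auc),
                 precision = precision, recall = recall, f1 = f1,
                 config = list(n_folds = n_folds, n_repeats = n_repeats,
                               n_trees = n_trees, mtry = mtry,
                               min_node = min_node,
                               neg_pos_ratio = neg_pos_ratio, seed = seed)),
            class = "qtg_cv")
}

#' @export
print.qtg_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation, %d repeats\n",
              x$config$n_folds, x$config$n_repeats))
  cat(sprintf("  AUC-ROC: mean %.3f (sd %.3f)\n", x$mean, x$sd))
  cat(sprintf("  at threshold 0.5: precision %.3f, recall %.3f, F1 %.3f\n",
              x$precision, x$recall, x$f1))
  invisible(x)
}

#' Grid search over ensemble hyperparameters
#'
#' Evaluates every grid row with [qtg_cv()] under the same seed and picks
#' the configuration with the highest mean AUC-ROC; ties break toward
#' fewer trees, then a smaller negative:positive ratio, so the result is
#' deterministic.
#'
#' @inheritParams qtg_cv
#' @param grid data.frame whose columns are any of `n_trees`, `mtry`,
#'   `min_node`, `neg_pos_ratio`; one row per candidate configuration.
#' @return List with `best` (the winning row, as a one-row data.frame) and
#'   `surface` (the grid with `mean_auc` and `sd_auc` columns).
#' @export
qtg_tune <- function(features, positives, grid, n_folds = 5,
                     n_repeats = 10, seed = 1L) {
  if (!nrow(grid)) stop("empty hyperparameter grid")
  defaults <- list(n_trees = 200, mtry = NULL, min_node = 1,
                   neg_pos_ratio = 1)
  surface <- grid
  surface$mean_auc <- surface$sd_auc <- NA_real_
  for (i in seq_len(nrow(grid))) {
    cfg <- utils::modifyList(defaults, as.list(grid[i, , drop = FALSE]))
    cv <- qtg_cv(features, positives, n_folds = n_folds,
                 n_repeats = n_repeats, n_trees = cfg$n_trees,
                 mtry = cfg$mtry, min_node = cfg$min_node,
                 neg_pos_ratio = cfg$neg_pos_ratio, seed = seed)
    surface$mean_auc[i] <- cv$mean
    surface$sd_auc[i] <- cv$sd
  }
  ord <- order(-surface$mean_auc,
               if (!is.null(surface$n_trees)) surface$n_trees else
                 rep(0, nrow(surface)),
               if (!is.null(surface$neg_pos_ratio)) surface$neg_pos_ratio
               else rep(0, nrow(surface)))
  list(best = grid[ord[1], , drop = FALSE], surface = surface)
}

#' Leave-one-out feature importance
#'
#' The importance of a feature is the drop in mean cross-validation
#' AUC-ROC when it is removed from the table, with the same seed (hence
#' the same negative draws and fold splits) used for the baseline and
#' every reduced model.  Redundant copies of an informative feature share
#' their importance, so correlated features shrink each other's scores.
#'
#' @inheritParams qtg_cv
#' @return Named numeric vector: feature -> AUC reduction (positive =
#'   removal hurts), with attribute `baseline` (full-table mean AUC).
#' @export
qtg_importance <- function(features, positives, n_folds = 5,
                           n_repeats = 10, n_trees = 200,
                           neg_pos_ratio = 1, seed = 1L) {
  x <- as.matrix(features)
  if (ncol(x) < 2) stop("leave-one-out importance needs >= 2 features")
  base <- qtg_cv(features, positives, n_folds = n_folds,
                 n_repeats = n_repeats, n_trees = n_trees,
                 neg_pos_ratio = neg_pos_ratio, seed = seed)$mean
  delta <- stats::setNames(numeric(ncol(x)), colnames(x))
  for (j in seq_len(ncol(x))) {
    red <- qtg_features(x[, -j, drop = FALSE], kinds = features$kinds[-j])
    delta[j] <- base - qtg_cv(red, positives, n_folds = n_folds,
                              n_repeats = n_repeats, n_trees = n_trees,
                              neg_pos_ratio = neg_pos_ratio,
                              seed = seed)$mean
  }
  attr(delta, "baseline") <- base
  delta
}
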