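#' Random-forest configuration
#'
#' @param ntree number of trees (default 500).
#' @param mtry predictor-subset size per node, or `"tune"` to optimize
#'   by repeated stratified 10-fold cross-validation.
#' @param min_node_size minimum node size before splitting stops
#'   (default 1: grow to purity).
#' @param cv_folds,cv_repeats cross-validation layout used when tuning.
#' @param mtry_grid grid of values tried when tuning; default is the
#'   neighborhood `floor(sqrt(p)) - 2 ... floor(sqrt(p)) + 2`
#'   intersected with `[1, p]`.
#' @param seed integer seed.
#' @return a `forest_config` list.
#' @export
forest_config <- function(ntree = 500L, mtry = "tune", min_node_size = 1L,
                          cv_folds = 10L, cv_repeats = 3L, mtry_grid = NULL,
                          seed = 1L) {
  check_count(ntree, "ntree")
  if (!identical(mtry, "tune")) check_count(mtry, "mtry")
  check_count(cv_folds, "cv_folds", min = 2)
  structure(list(ntree = as.integer(ntree), mtry = mtry,
                 min_node_size = as.integer(min_node_size),
                 cv_folds = as.integer(cv_folds),
                 cv_repeats = as.integer(cv_repeats),
                 mtry_grid = mtry_grid, seed = as.integer(seed)),
            class = "forest_config")
}

default_mtry_grid <- function(p) {
  g <- floor(sqrt(p)) + (-2:2)
  sort(unique(pmin(pmax(g, 1L), p)))
}

forest_call <- function(x, y01, xtest, ntree, mtry, min_node_size, per_tree) {
  .forest_cpp(as.matrix(x), as.integer(y01),
              if (is.null(xtest)) matrix(numeric(0), 0, ncol(x)) else as.matrix(xtest),
              as.integer(ntree), as.integer(mtry), as.integer(min_node_size),
              isTRUE(per_tree))
}

#' Grow a random forest and compute mean-decrease-Gini importance
#'
#' Each of `ntree` trees is grown on a bootstrap sample of size n; at
#' every node `mtry` features are drawn uniformly without replacement
#' and the split maximizing the weighted Gini impurity decrease is
#' taken (candidates are midpoints between consecutive sorted distinct
#' values; ties go to the lowest feature index, then lowest threshold).
#' Trees grow until pure or `min_node_size`. Per-feature MDG is the sum
#' over nodes split on the feature of the node-proportion-weighted Gini
#' decrease, divided by `ntree`. Bit-reproducible given the seed.
#'
#' @param x samples x features matrix.
#' @param y binary labels.
#' @param config a [forest_config()]; `mtry = "tune"` runs [tune_mtry()]
#'   first.
#' @param keep_per_tree keep the per-tree importance matrix and
#'   per-tree root/leaf impurities (for conservation checks).
#' @return a `forest_importance`: `mdg` (named), `mtry`, `oob_error`,
#'   `ntree`, and when requested `per_tree`, `root_gini`, `leaf_gini`;
#'   plus `cv_table` when mtry was tuned.
#' @export
grow_forest <- function(x, y, config = forest_config(), keep_per_tree = FALSE) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("F%04d", seq_len(ncol(x)))
  y01 <- as_binary_labels(y)
  if (min(table(y01)) < 2L)
    stop("grow_forest: need >= 2 samples per class", call. = FALSE)
  cv_table <- NULL
  mtry <- config$mtry
  if (identical(mtry, "tune")) {
    tuned <- tune_mtry(x, y01, config)
    mtry <- tuned$mtry
    cv_table <- tuned$table
  }
  if (mtry > ncol(x))
    stop(sprintf("grow_forest: mtry (%d) exceeds feature count (%d)", mtry, ncol(x)),
         call. = FALSE)
  set.seed(config$seed)
  res <- forest_call(x, y01, NULL, config$ntree, mtry, config$min_node_size,
                     keep_per_tree)
  mdg <- setNames(as.numeric(res$mdg), colnames(x))
  votes <- res$oob_votes
  has <- rowSums(votes) > 0
  pred <- as.integer(votes[, 2] > votes[, 1])    # tie -> class 0
  oob_error <- mean(pred[has] != y01[has])
  out <- list(mdg = mdg, mtry = as.integer(mtry), oob_error = oob_error,
              ntree = config$ntree, cv_table = cv_table)
  if (keep_per_tree) {
    rownames(res$per_tree) <- colnames(x)
    out$per_tree <- res$per_tree
    out$root_gini <- as.numeric(res$root_gini)
    out$leaf_gini <- as.numeric(res$leaf_gini)
  }
  structure(out, class = "forest_importance")
}

#' @export
print.forest_importance <- function(x, ...) {
  cat(sprintf("forest_importance: %d trees, mtry %d, OOB error %.3f\n",
              x$ntree, x$mtry, x$oob_error))
  print(head(sort(x$mdg, decreasing = TRUE), 10))
  invisible(x)
}

stratified_folds <- function(y01, k) {
  fold <- integer(length(y01))
  for (cls in c(0, 1)) {
    idx <- sample(which(y01 == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Tune mtry by repeated stratified cross-validation
#'
#' For every grid value, `cv_repeats` rounds of stratified
#' `cv_folds`-fold cross-validation are run (folds reshuffled per
#' round, shared across grid values within a round); the value with
#' the highest mean held-out accuracy wins, ties to the smallest mtry.
#' When a class has fewer members than folds, stratification degrades
#' to as-even-as-possible assignment and folds whose training half
#' lacks a class are skipped.
#'
#' @param x samples x features matrix.
#' @param y binary labels.
#' @param config a [forest_config()].
#' @return list with `mtry` (chosen) and `table` (mtry, mean_accuracy).
#' @export
tune_mtry <- function(x, y, config = forest_config()) {
  x <- as.matrix(x)
  y01 <- as_binary_labels(y)
  grid <- config$mtry_grid
  if (is.null(grid)) grid <- default_mtry_grid(ncol(x))
  grid <- sort(unique(as.integer(grid)))
  if (!length(grid)) stop("tune_mtry: empty mtry grid", call. = FALSE)
  k <- min(config$cv_folds, length(y01))
  set.seed(config$seed)
  acc <- matrix(NA_real_, length(grid), config$cv_repeats * k)
  col <- 0L
  for (rep in seq_len(config$cv_repeats)) {
    fold <- stratified_folds(y01, k)
    for (f in seq_len(k)) {
      col <- col + 1L
      tr <- fold != f; te <- !tr
      if (length(unique(y01[tr])) < 2L || !any(te)) next
      for (gi in seq_along(grid)) {
        if (grid[gi] > ncol(x)) next
        res <- forest_call(x[tr, , drop = FALSE], y01[tr], x[te, , drop = FALSE],
                           config$ntree, grid[gi], config$min_node_size, FALSE)
        pred <- as.integer(res$test_votes[, 2] > res$test_votes[, 1])
        acc[gi, col] <- mean(pred == y01[te])
      }
    }
  }
  mean_acc <- rowMeans(acc, na.rm = TRUE)
  best <- grid[which.max(mean_acc)]          # which.max takes the first: smallest mtry
  list(mtry = best, table = data.frame(mtry = grid, mean_accuracy = mean_acc))
}

#' Rank features by mean decrease Gini
#'
#' @param importance a `forest_importance`.
#' @param top_k number of top rows to return (default 15, the usual
#'   plotting depth).
#' @return data.frame: probe_id, mdg, rank; sorted by MDG descending,
#'   ties by probe_id.
#' @export
rank_importance <- function(importance, top_k = 15L) {
  mdg <- importance$mdg
  if (!length(mdg)) stop("rank_importance: empty importance", call. = FALSE)
  ord <- order(-mdg, names(mdg))
  out <- data.frame(probe_id = names(mdg)[ord], mdg = unname(mdg[ord]),
                    rank = seq_along(mdg), stringsAsFactors = FALSE)
  head(out, top_k)
}
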