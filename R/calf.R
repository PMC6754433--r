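## CALF: greedy forward selection of features with weights restricted
## to +1/-1, scored against the binary outcome by Pearson correlation
## (default) or AUC. Features are z-scored on the training samples so
## the unit weights act on a common scale. For the Pearson metric the
## greedy sweep uses exact closed-form updates of cov(score, y) and
## var(score) from the feature covariance matrix, so a full refit costs
## O(p) per step - this is what makes 2000-permutation and
## 2000-subsample reruns cheap.

zscore_features <- function(x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("F%04d", seq_len(ncol(x)))
  mu <- colMeans(x)
  sdv <- apply(x, 2L, sd)
  keep <- which(sdv > 0)
  z <- sweep(sweep(x[, keep, drop = FALSE], 2L, mu[keep]), 2L, sdv[keep], "/")
  list(z = z, keep = keep, skipped = colnames(x)[sdv == 0])
}

auc_stat <- function(scores, y01) {
  n1 <- sum(y01 == 1); n0 <- sum(y01 == 0)
  r <- rank(scores)
  (sum(r[y01 == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## Core greedy sweep on a pre-z-scored matrix. Returns column indices
## into z, the +/-1 weights, and the metric trajectory.
greedy_core <- function(z, y01, limit, metric = "pearson") {
  p <- ncol(z); n <- nrow(z)
  if (p == 0L) return(list(idx = integer(0), w = integer(0), traj = numeric(0)))
  sel <- integer(0); wts <- integer(0); traj <- numeric(0)
  current <- -Inf
  remaining <- rep(TRUE, p)
  if (metric == "pearson") {
    sdy <- sd(y01)
    cc <- crossprod(z) / (n - 1)              # feature covariances (diag = 1)
    cjy <- as.vector(crossprod(z, y01 - mean(y01))) / (n - 1)
    csy <- 0; vs <- 0
    csz <- numeric(p)                          # cov(score, z_j)
    for (step in seq_len(limit)) {
      vplus <- vs + 1 + 2 * csz
      vminus <- vs + 1 - 2 * csz
      rplus <- (csy + cjy) / (sqrt(pmax(vplus, 1e-12)) * sdy)
      rminus <- (csy - cjy) / (sqrt(pmax(vminus, 1e-12)) * sdy)
      rplus[!remaining] <- -Inf
      rminus[!remaining] <- -Inf
      best <- max(rplus, rminus)
      if (!(best > current)) break
      cand_p <- which(rplus >= best - 1e-12)
      cand_m <- which(rminus >= best - 1e-12)
      j <- min(cand_p, cand_m)                 # lowest feature index first
      w <- if (j %in% cand_p) 1L else -1L      # +1 before -1 on ties
      sel <- c(sel, j); wts <- c(wts, w)
      traj <- c(traj, if (w == 1L) rplus[j] else rminus[j])
      current <- traj[length(traj)]
      csy <- csy + w * cjy[j]
      vs <- vs + 1 + 2 * w * csz[j]
      csz <- csz + w * cc[, j]
      remaining[j] <- FALSE
    }
  } else if (metric == "auc") {
    score <- numeric(n)
    for (step in seq_len(limit)) {
      best <- current; bj <- 0L; bw <- 0L
      for (j in which(remaining)) {
        for (w in c(1L, -1L)) {
          a <- auc_stat(score + w * z[, j], y01)
          if (a > best + 1e-12) { best <- a; bj <- j; bw <- w }
        }
      }
      if (bj == 0L) break
      sel <- c(sel, bj); wts <- c(wts, bw)
      score <- score + bw * z[, bj]
      traj <- c(traj, best); current <- best
      remaining[bj] <- FALSE
    }
  } else stop(sprintf("unknown metric '%s'", metric), call. = FALSE)
  list(idx = sel, w = wts, traj = traj)
}

as_binary_labels <- function(y) {
  if (is.character(y) || is.factor(y)) {
    y <- as.character(y)
    lev <- unique(y)
    if (length(lev) != 2L) stop("labels must have exactly two classes", call. = FALSE)
    case <- if ("case" %in% lev) "case" else lev[1]
    y <- as.numeric(y == case)
  }
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1)) || length(unique(y)) != 2L)
    stop("labels must be binary with both classes present", call. = FALSE)
  y
}

#' CALF greedy forward selection with unit weights
#'
#' Selects, at each step, the (feature, sign) pair whose addition to
#' the running signed sum of z-scored features most improves the metric
#' against the binary labels; stops when no strict improvement is
#' possible or `limit` features are reached. Ties go to the lowest
#' feature index, then weight +1 before -1. Constant features are
#' skipped and logged.
#'
#' @param x samples x features matrix of candidate markers.
#' @param y binary labels (0/1, or a two-level factor; level "case" is
#'   the positive class).
#' @param limit maximum number of features (default 10).
#' @param metric `"pearson"` (Pearson correlation of the signed score
#'   with the labels, sign folded into the weights) or `"auc"`.
#' @return a `calf_model`: `features` (probe_id, weight, in selection
#'   order), `metric`, `trajectory` (strictly increasing), `final_metric`,
#'   `limit`, `skipped`.
#' @export
greedy_fit <- function(x, y, limit = 10L, metric = c("pearson", "auc")) {
  metric <- match.arg(metric)
  y01 <- as_binary_labels(y)
  if (min(sum(y01 == 1), sum(y01 == 0)) < 2L)
    stop("greedy_fit: need >= 2 samples per class", call. = FALSE)
  zs <- zscore_features(x)
  fit <- greedy_core(zs$z, y01, limit = limit, metric = metric)
  ids <- colnames(zs$z)[fit$idx]
  structure(list(
    features = data.frame(probe_id = ids, weight = fit$w, stringsAsFactors = FALSE),
    metric = metric,
    trajectory = fit$traj,
    final_metric = if (length(fit$traj)) fit$traj[length(fit$traj)] else NA_real_,
    limit = as.integer(limit),
    skipped = zs$skipped
  ), class = "calf_model")
}

#' @export
print.calf_model <- function(x, ...) {
  cat(sprintf("calf_model (%s): %d feature(s), final metric %.4f\n",
              x$metric, nrow(x$features), x$final_metric))
  print(x$features)
  invisible(x)
}

#' Predict the CALF score for new samples
#'
#' The signed sum of the selected features after z-scoring with the
#' supplied centering/scaling statistics (by default the new data's own).
#'
#' @param object a `calf_model`.
#' @param x samples x features matrix containing the selected features.
#' @param ... unused.
#' @return numeric score vector.
#' @export
predict.calf_model <- function(object, x, ...) {
  ids <- object$features$probe_id
  xm <- as.matrix(x[, ids, drop = FALSE])
  z <- scale(xm)
  z[, apply(xm, 2, sd) == 0] <- 0
  as.vector(z %*% object$features$weight)
}

#' Permutation test of the CALF final metric
#'
#' Labels are permuted uniformly `n_perm` times and the full greedy
#' procedure (same limit, same stopping rule) is rerun per permutation.
#' The empirical p is `max(b, 1) / n_perm` with `b` the number of
#' permuted final metrics at or above the observed one; with 2000
#' permutations and strong separation the attainable floor is exactly
#' 5.0e-4. The `(b + 1) / (n_perm + 1)` estimator is available via
#' `estimator = "add_one"`.
#'
#' @param x,y,limit,metric as in [greedy_fit()].
#' @param n_perm number of label permutations (default 2000; fewer than
#'   100 draws a resolution warning).
#' @param seed integer seed (the test is deterministic given it).
#' @param estimator `"floor"` (default) or `"add_one"`.
#' @return a `permutation_result`: observed, permuted (length n_perm),
#'   p, n_perm, seed, estimator.
#' @export
permutation_test <- function(x, y, limit = 10L, metric = c("pearson", "auc"),
                             n_perm = 2000L, seed = 1L,
                             estimator = c("floor", "add_one")) {
  metric <- match.arg(metric)
  estimator <- match.arg(estimator)
  if (n_perm < 100L) warning("permutation_test: n_perm < 100 gives poor p resolution")
  y01 <- as_binary_labels(y)
  zs <- zscore_features(x)
  obs <- greedy_core(zs$z, y01, limit, metric)
  observed <- obs$traj[length(obs$traj)]
  set.seed(seed)
  permuted <- vapply(seq_len(n_perm), function(i) {
    yp <- sample(y01)
    tr <- greedy_core(zs$z, yp, limit, metric)$traj
    tr[length(tr)]
  }, numeric(1))
  b <- sum(permuted >= observed)
  p <- if (estimator == "floor") max(b, 1) / n_perm else (b + 1) / (n_perm + 1)
  structure(list(observed = observed, permuted = permuted, p = p,
                 n_perm = as.integer(n_perm), seed = seed, estimator = estimator),
            class = "permutation_result")
}

#' Subsampling stability selection for CALF
#'
#' Each trial draws `ceiling(fraction * n)` samples per class without
#' replacement (class-stratified), reruns the greedy selection on the
#' subsample (features re-z-scored on the subsample), and counts how
#' often each feature is selected.
#'
#' @param x,y,limit,metric as in [greedy_fit()].
#' @param n_trials number of subsampling trials (default 2000).
#' @param fraction per-class subsample fraction in (0, 1] (default 0.8).
#' @param min_count default count threshold used by [consensus_markers()]
#'   (750 of 2000).
#' @param seed integer seed.
#' @return a `stability_result`: `counts` (named, per candidate feature),
#'   n_trials, fraction, min_count, seed.
#' @export
stability_selection <- function(x, y, limit = 10L, metric = c("pearson", "auc"),
                                n_trials = 2000L, fraction = 0.8,
                                min_count = 750L, seed = 1L) {
  metric <- match.arg(metric)
  if (fraction <= 0 || fraction > 1)
    stop("stability_selection: fraction must be in (0, 1]", call. = FALSE)
  y01 <- as_binary_labels(y)
  idx1 <- which(y01 == 1); idx0 <- which(y01 == 0)
  if (min(length(idx1), length(idx0)) < 3L)
    stop("stability_selection: need >= 3 samples per class", call. = FALSE)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("F%04d", seq_len(ncol(x)))
  m1 <- ceiling(fraction * length(idx1))
  m0 <- ceiling(fraction * length(idx0))
  counts <- setNames(integer(ncol(x)), colnames(x))
  set.seed(seed)
  for (trial in seq_len(n_trials)) {
    take <- c(idx1[sample.int(length(idx1), m1)], idx0[sample.int(length(idx0), m0)])
    zs <- zscore_features(x[take, , drop = FALSE])
    fit <- greedy_core(zs$z, y01[take], limit, metric)
    ids <- colnames(zs$z)[fit$idx]
    counts[ids] <- counts[ids] + 1L
  }
  structure(list(counts = counts, n_trials = as.integer(n_trials),
                 fraction = fraction, min_count = as.integer(min_count),
                 seed = seed),
            class = "stability_result")
}

#' Consensus markers: stable features also in the full-data model
#'
#' Intersects the features selected in at least `min_count` stability
#' trials with the full-data model's selected set; ordered by stability
#' count descending, ties broken by full-model selection order.
#'
#' @param full_model a `calf_model` fitted on all samples.
#' @param stability a `stability_result` from the same candidate set.
#' @param min_count stability count threshold (default 750).
#' @return data.frame: probe_id, stability_count, weight,
#'   selection_order; zero rows when nothing is stable.
#' @export
consensus_markers <- function(full_model, stability, min_count = 750L) {
  stable <- names(stability$counts)[stability$counts >= min_count]
  ids <- intersect(stable, full_model$features$probe_id)
  ord <- match(ids, full_model$features$probe_id)
  out <- data.frame(probe_id = ids,
                    stability_count = unname(stability$counts[ids]),
                    weight = full_model$features$weight[ord],
                    selection_order = ord,
                    stringsAsFactors = FALSE)
  out[order(-out$stability_count, out$selection_order), , drop = FALSE]
}
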