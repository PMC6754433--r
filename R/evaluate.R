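#' Area under the ROC curve
#'
#' Mann-Whitney formulation with tie correction: the probability a
#' random case scores above a random control, ties counted 1/2 — equal
#' to the trapezoidal area under the empirical ROC.
#'
#' @param scores numeric scores (higher = more case-like).
#' @param labels binary labels (1/"case" = positive).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("roc_auc: both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Covariate-adjusted AUC via logistic regression
#'
#' Fits `label ~ marker + covariates` by IRLS (stats::glm, binomial
#' link, tolerance 1e-8, up to 100 iterations) and computes the AUC of
#' the fitted linear predictor. If separation is detected (diverging
#' coefficients or non-convergence) the marker's unadjusted AUC is
#' reported instead and the fallback is logged in the result.
#'
#' @param marker numeric marker values.
#' @param labels binary labels.
#' @param covariates data.frame of adjustment covariates (e.g. age,
#'   sex), or NULL for no adjustment.
#' @param n_boot bootstrap replications for the CI (default 2000).
#' @param level confidence level (default 0.95).
#' @param seed seed for the bootstrap.
#' @return a `roc_summary`: auc, ci_low, ci_high, n_boot, threshold,
#'   sensitivity, specificity, adjusted, covariates, coefficients,
#'   fallback (NULL or reason).
#' @export
adjusted_auc <- function(marker, labels, covariates = NULL,
                         n_boot = 2000L, level = 0.95, seed = 1L) {
  y <- as_binary_labels(labels)
  fallback <- NULL
  coefs <- NULL
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0L) {
    lp <- marker
    adjusted <- FALSE
  } else {
    df <- data.frame(y = y, marker = marker, as.data.frame(covariates))
    fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial(),
                                control = list(epsilon = 1e-8, maxit = 100)))
    coefs <- coef(fit)
    if (!fit$converged || any(abs(coefs[-1]) > 1e3, na.rm = TRUE)) {
      fallback <- "separation detected in logistic fit; reporting unadjusted marker AUC"
      lp <- marker
      adjusted <- FALSE
    } else {
      lp <- fit$linear.predictors
      adjusted <- TRUE
    }
  }
  auc <- roc_auc(lp, y)
  ci <- bootstrap_ci(lp, y, n_boot = n_boot, level = level, seed = seed)
  op <- operating_point(lp, y)
  structure(list(auc = auc, ci_low = ci[1], ci_high = ci[2],
                 n_boot = as.integer(n_boot),
                 threshold = op$threshold, sensitivity = op$sensitivity,
                 specificity = op$specificity, adjusted = adjusted,
                 covariates = if (is.null(covariates)) character(0)
                              else names(as.data.frame(covariates)),
                 coefficients = coefs, fallback = fallback),
            class = "roc_summary")
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf("AUC %.3f (%.0f%% CI %.3f-%.3f, %d bootstrap reps)%s\n",
              x$auc, 95, x$ci_low, x$ci_high, x$n_boot,
              if (x$adjusted) sprintf(" adjusted for %s",
                                      paste(x$covariates, collapse = ", ")) else ""))
  cat(sprintf("operating point (Youden): threshold %.4g, sensitivity %.3f, specificity %.3f\n",
              x$threshold, x$sensitivity, x$specificity))
  if (!is.null(x$fallback)) cat("note:", x$fallback, "\n")
  invisible(x)
}

#' Percentile bootstrap confidence interval for the AUC
#'
#' Class-stratified resampling with replacement (cases and controls
#' resampled within class, so every replicate retains both classes);
#' percentile interval of the bootstrap AUC distribution.
#'
#' @param scores,labels as in [roc_auc()].
#' @param n_boot replications (default 2000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return numeric `c(ci_low, ci_high)`.
#' @export
bootstrap_ci <- function(scores, labels, n_boot = 2000L, level = 0.95, seed = 1L) {
  y <- as_binary_labels(labels)
  i1 <- which(y == 1); i0 <- which(y == 0)
  set.seed(seed)
  stat <- vapply(seq_len(n_boot), function(b) {
    take <- c(sample(i1, length(i1), replace = TRUE),
              sample(i0, length(i0), replace = TRUE))
    roc_auc(scores[take], y[take])
  }, numeric(1))
  a <- (1 - level) / 2
  unname(quantile(stat, c(a, 1 - a), type = 7))
}

#' Operating point maximizing Youden's J
#'
#' Thresholds are the midpoints between consecutive sorted distinct
#' scores plus sentinels below and above the range; a sample is called
#' positive when its score exceeds the threshold. The threshold
#' maximizing J = sensitivity + specificity - 1 is returned; ties go
#' to the higher specificity (then the higher threshold).
#'
#' @param scores,labels as in [roc_auc()].
#' @return list(threshold, sensitivity, specificity, youden_j).
#' @export
operating_point <- function(scores, labels) {
  y <- as_binary_labels(labels)
  u <- sort(unique(scores))
  thr <- c(u[1] - 1, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2, u[length(u)] + 1)
  best <- list(threshold = thr[1], sensitivity = NA, specificity = NA, youden_j = -Inf)
  for (t in thr) {
    sens <- mean(scores[y == 1] > t)
    spec <- mean(scores[y == 0] <= t)
    j <- sens + spec - 1
    if (j > best$youden_j + 1e-12 ||
        (abs(j - best$youden_j) <= 1e-12 && spec > best$specificity + 1e-12)) {
      best <- list(threshold = t, sensitivity = sens, specificity = spec, youden_j = j)
    }
  }
  best
}

#' Correlate a marker with clinical severity scales
#'
#' Pearson correlation (with t-based two-sided p) of the marker against
#' each supplied clinical scale, pairwise over complete observations.
#'
#' @param marker numeric marker values.
#' @param clinical data.frame of clinical scores (e.g. assq_total,
#'   ados_total, iq), rows aligned with `marker`.
#' @return data.frame: scale, n, r, p.
#' @export
correlate_clinical <- function(marker, clinical) {
  clinical <- as.data.frame(clinical)
  res <- lapply(names(clinical), function(nm) {
    v <- as.numeric(clinical[[nm]])
    ok <- complete.cases(marker, v)
    ct <- pearson_test(marker[ok], v[ok])
    data.frame(scale = nm, n = sum(ok), r = ct$r, p = ct$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
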