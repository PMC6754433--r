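#' Design specification for probe-wise models
#'
#' @param response sample-sheet column with the two-level group factor
#'   (level `"case"` is the coefficient of interest when present,
#'   otherwise the first level).
#' @param covariates optional character vector of adjustment columns
#'   (e.g. age, sex, estimated cell proportions). The default screening
#'   model carries no covariates; effect sizes are reported in beta
#'   units either way.
#' @return a `design_spec` list.
#' @export
design_spec <- function(response = "group", covariates = NULL) {
  structure(list(response = response, covariates = covariates),
            class = "design_spec")
}

build_design_matrix <- function(samples, design) {
  miss <- setdiff(c(design$response, design$covariates), names(samples))
  if (length(miss))
    stop(sprintf("design columns not in sample sheet: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  grp <- samples[[design$response]]
  lev <- unique(grp)
  if (length(lev) != 2L)
    stop("fit_probe_models: response must have exactly two levels", call. = FALSE)
  case <- if ("case" %in% lev) "case" else lev[1]
  df <- data.frame(group = as.numeric(grp == case))
  for (cv in design$covariates) {
    v <- samples[[cv]]
    df[[cv]] <- if (is.character(v) || is.factor(v)) v else as.numeric(v)
  }
  x <- model.matrix(~ ., data = df)
  q <- qr(x)
  if (q$rank < ncol(x)) {
    dropped <- colnames(x)[q$pivot[(q$rank + 1L):ncol(x)]]
    stop(sprintf("fit_probe_models: rank-deficient design; collinear column(s): %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  list(x = x, case = case)
}

#' Probe-wise linear models on beta values
#'
#' Ordinary least squares per probe (all probes at once via a QR of the
#' common design matrix). The group coefficient is adjusted for any
#' covariates; `delta_beta` is always the raw unadjusted case-minus-
#' control difference of group means, kept separate for effect-size
#' filtering in beta units.
#'
#' @param beta probes x samples matrix.
#' @param samples sample sheet (rows aligned with `colnames(beta)`).
#' @param design a [design_spec()].
#' @return data.frame: probe_id, delta_beta, coefficient, s2 (residual
#'   variance), df_residual, stdev_unscaled.
#' @export
fit_probe_models <- function(beta, samples, design = design_spec()) {
  bd <- build_design_matrix(samples, design)
  x <- bd$x
  n <- nrow(x)
  if (n <= ncol(x))
    stop("fit_probe_models: need more samples than design columns", call. = FALSE)
  fit <- lm.fit(x, t(beta))
  coefs <- t(fit$coefficients)
  res <- t(fit$residuals)
  d <- n - ncol(x)
  s2 <- rowSums(res^2) / d
  xtx_inv <- chol2inv(chol(crossprod(x)))
  su <- sqrt(xtx_inv[colnames(x) == "group", colnames(x) == "group"])
  grp <- samples[[design$response]]
  case <- grp == bd$case
  delta <- rowMeans(beta[, case, drop = FALSE]) - rowMeans(beta[, !case, drop = FALSE])
  data.frame(probe_id = rownames(beta),
             delta_beta = unname(delta),
             coefficient = unname(coefs[, "group"]),
             s2 = unname(s2),
             df_residual = d,
             stdev_unscaled = su,
             stringsAsFactors = FALSE)
}

## Solve trigamma(y) = x by damped Newton iteration (monotone, convex).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif) < 1e-10 * y) break
  }
  y
}

#' Empirical-Bayes moderation of probe variances
#'
#' Fits the scaled-F marginal model for residual variances by moment
#' matching on the log scale: with `e = log(s2) - digamma(d/2) +
#' log(d/2)`, the prior degrees of freedom `d0` solve
#' `trigamma(d0/2) = var(e) - trigamma(d/2)` and the prior variance is
#' `s02 = exp(mean(e) + digamma(d0/2) - log(d0/2))`. When the excess
#' variance is nonpositive, `d0 = Inf` (pure pooling: every posterior
#' variance equals `s02`). Posterior variances are
#' `(d0*s02 + d*s2) / (d0 + d)`; if coefficients are supplied, the
#' moderated t and its two-sided p on `d0 + d` degrees of freedom are
#' returned as well.
#'
#' @param s2 per-probe residual variances.
#' @param d residual degrees of freedom (scalar).
#' @param coefficients,stdev_unscaled optional; enable t and p output.
#' @param d0 optional override of the prior degrees of freedom (0 gives
#'   the ordinary t; Inf gives full pooling).
#' @return a `moderation_fit`: d0, s0_2, post_var, df_total, and (when
#'   coefficients are given) t and p.
#' @export
moderate_variances <- function(s2, d, coefficients = NULL, stdev_unscaled = NULL,
                               d0 = NULL) {
  if (length(s2) < 10L)
    stop("moderate_variances: need at least 10 probes", call. = FALSE)
  s2 <- pmax(s2, 1e-12)
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  if (is.null(d0)) {
    evar <- var(e) - trigamma(d / 2)
    d0 <- if (evar > 0) 2 * trigamma_inverse(evar) else Inf
  }
  ## d0 = Inf: the scaled-F marginal collapses to a point mass, whose ML
  ## scale is the arithmetic mean of the variances; d0 = 0 leaves the
  ## prior scale as the plain geometric-moment estimate
  s0_2 <- if (!is.finite(d0)) mean(s2)
          else if (d0 > 0) exp(emean + digamma(d0 / 2) - log(d0 / 2))
          else exp(emean)
  post_var <- if (is.finite(d0)) {
    if (d0 == 0) s2 else (d0 * s0_2 + d * s2) / (d0 + d)
  } else rep(s0_2, length(s2))
  ## total df capped at the pooled residual df: the prior cannot carry
  ## more information than the whole dataset supplies
  df_total <- min(d0 + d, length(s2) * d)
  out <- list(d0 = d0, s0_2 = s0_2, post_var = post_var, df_total = df_total)
  if (!is.null(coefficients)) {
    tmod <- coefficients / (stdev_unscaled * sqrt(post_var))
    out$t <- tmod
    out$p <- 2 * pt(-abs(tmod), df = df_total)
  }
  structure(out, class = "moderation_fit")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values, `q_i = min over j with p_(j) >= p_(i) of
#' p_(j) * m / j`, clipped at 1 and returned in the input order.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return vector of FDR-adjusted values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("bh_adjust: p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Call differentially methylated positions
#'
#' Runs [fit_probe_models()], [moderate_variances()] and [bh_adjust()]
#' and applies the pass flags at the given thresholds.
#'
#' @param beta probes x samples matrix.
#' @param samples sample sheet.
#' @param design a [design_spec()].
#' @param fdr_max,delta_min thresholds for the pass flags (defaults
#'   0.1 and 0.1).
#' @return a `dmp_table` data.frame: probe_id, delta_beta, coefficient,
#'   s2, df_residual, t, df_total, p, fdr, pass_fdr, pass_delta.
#' @export
call_dmps <- function(beta, samples, design = design_spec(),
                      fdr_max = 0.1, delta_min = 0.1) {
  fits <- fit_probe_models(beta, samples, design)
  mod <- moderate_variances(fits$s2, fits$df_residual[1],
                            coefficients = fits$coefficient,
                            stdev_unscaled = fits$stdev_unscaled)
  fdr <- bh_adjust(mod$p)
  out <- data.frame(probe_id = fits$probe_id,
                    delta_beta = fits$delta_beta,
                    coefficient = fits$coefficient,
                    s2 = fits$s2,
                    df_residual = fits$df_residual,
                    t = mod$t,
                    df_total = mod$df_total,
                    p = mod$p,
                    fdr = fdr,
                    pass_fdr = fdr <= fdr_max,
                    pass_delta = abs(fits$delta_beta) >= delta_min,
                    stringsAsFactors = FALSE)
  attr(out, "moderation") <- mod[c("d0", "s0_2")]
  class(out) <- c("dmp_table", "data.frame")
  out
}

#' Select DMPs by FDR and effect size
#'
#' Keeps rows with `fdr <= fdr_max` and `|delta_beta| >= delta_min`,
#' sorted by fdr ascending then `|delta_beta|` descending, ties broken
#' by probe_id.
#'
#' @param table a `dmp_table` from [call_dmps()].
#' @param fdr_max,delta_min selection thresholds (defaults 0.1, 0.1).
#' @return the selected subset, reordered.
#' @export
select_dmps <- function(table, fdr_max = 0.1, delta_min = 0.1) {
  if (nrow(table) == 0L) stop("select_dmps: empty table", call. = FALSE)
  keep <- table$fdr <= fdr_max & abs(table$delta_beta) >= delta_min
  out <- table[keep, , drop = FALSE]
  out[order(out$fdr, -abs(out$delta_beta), out$probe_id), , drop = FALSE]
}

#' Two-group Student's t-test and Pearson correlation
#'
#' `two_group_test` is the pooled-variance two-sample t-test; groups
#' with zero pooled variance return t = 0, p = 1 when the means agree.
#' `pearson_test` is Pearson's r with the t-based two-sided p.
#'
#' @param x_case,x_control numeric vectors (>= 2 values each).
#' @return `two_group_test`: list(t, df, p); `pearson_test`: list(r, p).
#' @export
two_group_test <- function(x_case, x_control) {
  if (length(x_case) < 2L || length(x_control) < 2L)
    stop("two_group_test: need >= 2 values per group", call. = FALSE)
  n1 <- length(x_case); n2 <- length(x_control)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * var(x_case) + (n2 - 1) * var(x_control)) / df
  if (sp2 <= 0) {
    dm <- mean(x_case) - mean(x_control)
    return(list(t = if (dm == 0) 0 else sign(dm) * Inf,
                df = df, p = if (dm == 0) 1 else 0))
  }
  tt <- t.test(x_case, x_control, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' @param x,y paired numeric vectors with nonzero variance.
#' @rdname two_group_test
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) stop("pearson_test: unequal lengths", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("pearson_test: correlation undefined for a constant vector", call. = FALSE)
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
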