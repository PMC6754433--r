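## BMIQ: per-sample three-state beta-mixture fits for each probe
## chemistry, then quantile mapping of the type-II unmethylated (U) and
## methylated (M) states onto the type-I state distributions, with a
## linear "dilation" of the hemimethylated (H) interval between the two
## transformed boundaries. Type-I values are never touched.

#' Fit a three-state beta mixture by EM
#'
#' Components model the unmethylated (U), hemimethylated (H) and fully
#' methylated (M) states of a beta-value distribution. The E-step uses
#' exact beta densities; the M-step solves the weighted maximum-
#' likelihood equations for each component's shape parameters (Newton
#' iteration on the digamma system, warm-started from the previous
#' estimate; moment matching supplies the initial values).
#' Initialization is deterministic: observations are split at the
#' conventional methylation-state cutoffs (0.2 and 0.75), falling back
#' to the empirical terciles when a bin is nearly empty.
#'
#' @param values numeric vector of betas; clipped into (0, 1).
#' @param n_states number of components (fixed at 3).
#' @param tol convergence tolerance on the log-likelihood gain.
#' @param max_iter maximum EM iterations.
#' @param seed accepted for API stability; the fit is deterministic.
#' @param init optional `beta_mixture_fit` whose weights and shapes seed
#'   the EM (used to align the type-II state decomposition with the
#'   type-I one during BMIQ).
#' @return a `beta_mixture_fit`: `weights`, `shape1`, `shape2`, `means`
#'   (increasing, labelled U/H/M), `loglik`, `iterations`, and the
#'   responsibility matrix `resp` (rows sum to 1).
#' @export
fit_beta_mixture <- function(values, n_states = 3L, tol = 1e-4,
                             max_iter = 200L, seed = NULL, init = NULL) {
  if (length(values) < 50L)
    stop("fit_beta_mixture: need at least 50 values", call. = FALSE)
  if (n_states != 3L)
    stop("fit_beta_mixture: only 3-state fits are supported", call. = FALSE)
  x <- clip_beta(as.numeric(values))
  if (sd(x) < 1e-8)
    stop("fit_beta_mixture: degenerate data (all values identical)", call. = FALSE)

  moments_to_shapes <- function(m, v) {
    v <- pmin(pmax(v, 1e-6), m * (1 - m) * 0.999)
    s <- m * (1 - m) / v - 1
    c(shape1 = max(m * s, 1e-2), shape2 = max((1 - m) * s, 1e-2))
  }
  ## weighted-ML shapes: solve digamma(a) - digamma(a+b) = E_w[log x],
  ## digamma(b) - digamma(a+b) = E_w[log(1-x)] by damped Newton
  ml_shapes <- function(s_logx, s_log1mx, a, b) {
    for (i in 1:40) {
      dab <- digamma(a + b); tab <- trigamma(a + b)
      g1 <- digamma(a) - dab - s_logx
      g2 <- digamma(b) - dab - s_log1mx
      j11 <- trigamma(a) - tab; j22 <- trigamma(b) - tab; j12 <- -tab
      det <- j11 * j22 - j12 * j12
      if (!is.finite(det) || abs(det) < 1e-12) break
      da <- (g1 * j22 - g2 * j12) / det
      db <- (g2 * j11 - g1 * j12) / det
      step <- 1
      while (a - step * da <= 0 || b - step * db <= 0) step <- step / 2
      a <- a - step * da; b <- b - step * db
      if (abs(da) + abs(db) < 1e-8 * (a + b)) break
    }
    c(shape1 = min(max(a, 1e-2), 1e5), shape2 = min(max(b, 1e-2), 1e5))
  }
  if (!is.null(init)) {
    w <- init$weights; shape1 <- init$shape1; shape2 <- init$shape2
  } else {
    ## seed at the conventional methylation-state cutoffs; fall back to
    ## empirical terciles when a bin would be (near-)empty
    qs <- c(0.2, 0.75)
    grp <- findInterval(x, qs) + 1L
    if (min(tabulate(grp, 3L)) < 5L) {
      qs <- quantile(x, c(1 / 3, 2 / 3), names = FALSE, type = 7)
      grp <- findInterval(x, qs) + 1L
    }
    shape1 <- shape2 <- w <- numeric(3)
    for (k in 1:3) {
      xk <- x[grp == k]
      if (length(xk) < 2L) xk <- x        # collapsed tercile: fall back
      sh <- moments_to_shapes(mean(xk), max(var(xk), 1e-6))
      shape1[k] <- sh[1]; shape2[k] <- sh[2]; w[k] <- max(mean(grp == k), 1e-3)
    }
    w <- w / sum(w)
  }

  loglik <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(1:3, function(k) w[k] * dbeta(x, shape1[k], shape2[k]),
                   numeric(length(x)))
    tot <- rowSums(dens)
    tot[tot < 1e-300] <- 1e-300
    resp <- dens / tot
    new_loglik <- sum(log(tot))
    nk <- pmax(colSums(resp), 1e-8)
    w <- nk / length(x)
    lx <- log(x); l1x <- log1p(-x)
    for (k in 1:3) {
      sh <- ml_shapes(sum(resp[, k] * lx) / nk[k],
                      sum(resp[, k] * l1x) / nk[k],
                      shape1[k], shape2[k])
      shape1[k] <- sh[1]; shape2[k] <- sh[2]
    }
    if (is.finite(loglik) && new_loglik - loglik < tol) { loglik <- new_loglik; break }
    loglik <- new_loglik
  }

  means <- shape1 / (shape1 + shape2)
  ord <- order(means, -w)                 # ties in mean broken by weight
  dens <- vapply(ord, function(k) w[k] * dbeta(x, shape1[k], shape2[k]),
                 numeric(length(x)))
  tot <- pmax(rowSums(dens), 1e-300)
  structure(list(weights = w[ord], shape1 = shape1[ord], shape2 = shape2[ord],
                 means = means[ord], labels = c("U", "H", "M"),
                 loglik = loglik, iterations = it, resp = dens / tot),
            class = "beta_mixture_fit")
}

## Monotone per-sample map of type-II betas onto the type-I scale.
## Regions are delimited by the largest U-classified and smallest
## M-classified type-II value, so the map is piecewise monotone and
## globally nondecreasing.
bmiq_map_sample <- function(x2, fit1, fit2, sample_id) {
  cls <- max.col(fit2$resp, ties.method = "first")   # 1=U, 2=H, 3=M
  if (!any(cls == 1L) || !any(cls == 3L))
    stop(sprintf("bmiq_normalize: mixture fit failure for sample '%s' (missing U or M state)",
                 sample_id), call. = FALSE)
  t1 <- max(x2[cls == 1L])
  t2 <- min(x2[cls == 3L])
  ## the parametric quantile map is unstable in the far component tails
  ## (a tiny shape perturbation moves the 0.999-quantile a lot), so cap
  ## each mapped region at the stable bulk of its component CDF and let
  ## the dilation interpolation carry the rest of the H interval
  t1 <- min(t1, qbeta(0.95, fit2$shape1[1], fit2$shape2[1]))
  t2 <- max(t2, qbeta(0.05, fit2$shape1[3], fit2$shape2[3]))
  if (t1 >= t2) { t1 <- t2 <- (t1 + t2) / 2 }

  map_u <- function(v) qbeta(pbeta(v, fit2$shape1[1], fit2$shape2[1]),
                             fit1$shape1[1], fit1$shape2[1])
  map_m <- function(v) qbeta(pbeta(v, fit2$shape1[3], fit2$shape2[3],
                                   lower.tail = FALSE),
                             fit1$shape1[3], fit1$shape2[3], lower.tail = FALSE)
  y_lo <- map_u(t1)
  y_hi <- max(map_m(t2), y_lo)

  y <- numeric(length(x2))
  lo <- x2 <= t1
  hi <- x2 >= t2
  mid <- !lo & !hi
  y[lo] <- pmin(map_u(x2[lo]), y_lo)
  y[hi] <- pmax(map_m(x2[hi]), y_hi)
  if (any(mid))
    y[mid] <- y_lo + (x2[mid] - t1) / (t2 - t1) * (y_hi - y_lo)
  clip_beta(y)
}

#' BMIQ normalization of type-II probes
#'
#' Per sample: fit three-state beta mixtures separately to type-I and
#' type-II betas, map type-II U-state values onto the type-I U beta
#' distribution by quantile matching (likewise M), and carry the
#' intermediate H interval by linear dilation between the two
#' transformed boundaries. Type-I values are returned bit-identical;
#' within-sample ranks of type-II probes are preserved.
#'
#' @param dataset a `methyl_dataset` whose annotation has `design_type`.
#' @param tol,max_iter EM controls passed to [fit_beta_mixture()].
#' @param seed accepted for API stability; the procedure is deterministic.
#' @return the normalized `methyl_dataset`.
#' @export
bmiq_normalize <- function(dataset, tol = 1e-4, max_iter = 200L, seed = NULL) {
  validate_methyl_dataset(dataset)
  is2 <- dataset$annotation$design_type == "II"
  if (sum(!is2) < 50L || sum(is2) < 50L)
    stop("bmiq_normalize: need at least 50 probes of each design type", call. = FALSE)
  beta <- dataset$beta
  for (s in seq_len(ncol(beta))) {
    sid <- colnames(beta)[s]
    fit1 <- tryCatch(fit_beta_mixture(beta[!is2, s], tol = tol, max_iter = max_iter),
                     error = function(e) stop(sprintf(
                       "bmiq_normalize: mixture fit failure for sample '%s': %s",
                       sid, conditionMessage(e)), call. = FALSE))
    fit2 <- tryCatch(fit_beta_mixture(beta[is2, s], tol = tol, max_iter = max_iter,
                                      init = fit1),
                     error = function(e) stop(sprintf(
                       "bmiq_normalize: mixture fit failure for sample '%s': %s",
                       sid, conditionMessage(e)), call. = FALSE))
    beta[is2, s] <- bmiq_map_sample(beta[is2, s], fit1, fit2, sid)
  }
  out <- dataset
  out$beta <- beta
  out
}
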