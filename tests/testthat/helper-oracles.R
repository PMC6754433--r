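## Independent brute-force oracles used by the equivalence tests. These
## deliberately use the most literal definition of each quantity and
## share no code with the package implementations.

## BH step-up by direct definition: q_i = min over p_(j) >= p_(i) of p_(j)*m/j
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(which(ps >= ps[i] - 1e-15), function(j) ps[j] * m / j, numeric(1))
    q[i] <- min(c(cand, 1))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

## AUC by exhaustive pair counting, ties 1/2
auc_pairs <- function(scores, y) {
  ca <- scores[y == 1]; co <- scores[y == 0]
  tot <- 0
  for (a in ca) for (b in co) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(ca) * length(co))
}

## best single signed z-scored feature by exhaustive search
calf_step1_brute <- function(x, y) {
  z <- scale(x)
  best <- -Inf; bj <- NA; bw <- NA
  for (j in seq_len(ncol(z))) {
    if (sd(x[, j]) == 0) next
    for (w in c(1, -1)) {
      r <- cor(w * z[, j], y)
      if (r > best + 1e-12) { best <- r; bj <- j; bw <- w }
    }
  }
  list(feature = bj, weight = bw, metric = best)
}

## exhaustive best signed model of at most two features (the greedy run
## may legitimately stop after one, so singles are part of the search space)
calf_pair_brute <- function(x, y) {
  z <- scale(x)
  best <- calf_step1_brute(x, y)$metric
  p <- ncol(z)
  for (j in seq_len(p)) for (k in seq_len(p)) {
    if (k == j) next
    for (wj in c(1, -1)) for (wk in c(1, -1)) {
      s <- wj * z[, j] + wk * z[, k]
      if (sd(s) == 0) next
      best <- max(best, cor(s, y))
    }
  }
  best
}

## operating point by complete threshold enumeration
youden_brute <- function(scores, y) {
  thr <- sort(unique(c(scores - 1e-9, scores + 1e-9,
                       min(scores) - 1, max(scores) + 1)))
  best <- list(j = -Inf, sens = NA, spec = NA, thr = NA)
  for (t in thr) {
    sens <- mean(scores[y == 1] > t)
    spec <- mean(scores[y == 0] <= t)
    if (sens + spec - 1 > best$j + 1e-12) {
      best <- list(j = sens + spec - 1, sens = sens, spec = spec, thr = t)
    }
  }
  best
}

## logistic log-likelihood for a grid search oracle
logistic_loglik <- function(b0, b1, x, y) {
  eta <- b0 + b1 * x
  sum(y * eta - log1p(exp(eta)))
}

## synthetic cell-type reference: each discriminating probe is
## hypermethylated in exactly one of the six leukocyte types
ref_fixture <- function(seed = 61, L = 60) {
  set.seed(seed)
  r <- matrix(rbeta(L * 6, 2, 2), L, 6,
              dimnames = list(sprintf("cg%08d", 1:L),
                              c("B", "CD8T", "CD4T", "NK", "Mono", "Gran")))
  owner <- rep_len(1:6, L)
  for (i in seq_len(L)) { r[i, ] <- 0.12; r[i, owner[i]] <- 0.85 }
  r
}

## dataset whose betas are a known mixture of the reference columns
mix_dataset <- function(ref, w, noise_sd = 0) {
  y <- ref %*% t(w)
  if (noise_sd > 0) y <- y + matrix(rnorm(length(y), 0, noise_sd), nrow(y))
  y <- pmin(pmax(y, 1e-6), 1 - 1e-6)
  n <- ncol(y)
  colnames(y) <- sprintf("S%04d", 1:n)
  methyl_dataset(
    y, matrix(0.001, nrow(y), n, dimnames = dimnames(y)),
    matrix(10L, nrow(y), n, dimnames = dimnames(y)),
    data.frame(probe_id = rownames(y), chromosome = "1", design_type = "II",
               snp_flag = 0L, cross_reactive_flag = 0L, gene_symbol = "G",
               stringsAsFactors = FALSE),
    data.frame(sample_id = colnames(y),
               group = rep(c("case", "control"), length.out = n),
               age = 30, sex = "M", batch_id = "B1", iq = 100,
               ados_total = 3, assq_total = 10, stringsAsFactors = FALSE))
}

## small hand-built dataset for filter tests
toy_dataset <- function(np = 10L, n = 4L) {
  beta <- matrix(runif(np * n, 0.2, 0.8), np, n,
                 dimnames = list(sprintf("cg%08d", 1:np), sprintf("S%04d", 1:n)))
  detection_p <- matrix(0.001, np, n, dimnames = dimnames(beta))
  bead_count <- matrix(10L, np, n, dimnames = dimnames(beta))
  annotation <- data.frame(probe_id = rownames(beta),
                           chromosome = rep("1", np),
                           design_type = rep(c("I", "II"), length.out = np),
                           snp_flag = 0L, cross_reactive_flag = 0L,
                           gene_symbol = "G", stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = colnames(beta),
                        group = rep(c("case", "control"), length.out = n),
                        age = 30, sex = "M", batch_id = "B1",
                        iq = 100, ados_total = 3, assq_total = 10,
                        stringsAsFactors = FALSE)
  methyl_dataset(beta, detection_p, bead_count, annotation, samples)
}
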