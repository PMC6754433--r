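test_that("probe models reproduce textbook pooled statistics", {
  beta <- matrix(c(0.60, 0.62, 0.58, 0.50, 0.52, 0.48), nrow = 1,
                 dimnames = list("cg1", sprintf("S%d", 1:6)))
  samples <- data.frame(sample_id = colnames(beta),
                        group = rep(c("case", "control"), each = 3),
                        age = c(30, 31, 32, 29, 33, 28), sex = "M",
                        batch_id = "B1", stringsAsFactors = FALSE)
  fit <- fit_probe_models(beta, samples)
  expect_equal(fit$coefficient, 0.10, tolerance = 1e-12)
  expect_equal(fit$delta_beta, 0.10, tolerance = 1e-12)
  ## pooled variance by the textbook formula
  sp2 <- (2 * var(c(0.60, 0.62, 0.58)) + 2 * var(c(0.50, 0.52, 0.48))) / 4
  expect_equal(fit$s2, sp2, tolerance = 1e-12)
  expect_identical(fit$df_residual, 4L)

  ## a covariate identical to the group indicator is rank deficient
  samples$dup <- as.numeric(samples$group == "case")
  expect_error(fit_probe_models(beta, samples, design_spec(covariates = "dup")),
               "rank-deficient")

  ## an orthogonal covariate leaves the group coefficient unchanged
  samples$orth <- c(1, -1, 0, 1, -1, 0)
  fit2 <- fit_probe_models(beta, samples, design_spec(covariates = "orth"))
  expect_equal(fit2$coefficient, fit$coefficient, tolerance = 1e-10)
})

test_that("moderation limits recover the ordinary and fully pooled t", {
  set.seed(71)
  n <- 16
  beta <- matrix(rbeta(200 * n, 5, 5), 200,
                 dimnames = list(sprintf("cg%03d", 1:200), sprintf("S%d", 1:n)))
  samples <- data.frame(sample_id = colnames(beta),
                        group = rep(c("case", "control"), each = n / 2),
                        age = 30, sex = "M", batch_id = "B1")
  fit <- fit_probe_models(beta, samples)
  m0 <- moderate_variances(fit$s2, fit$df_residual[1], fit$coefficient,
                           fit$stdev_unscaled, d0 = 0)
  t_ord <- fit$coefficient / (fit$stdev_unscaled * sqrt(fit$s2))
  expect_equal(m0$t, t_ord, tolerance = 1e-12)
  mInf <- moderate_variances(fit$s2, fit$df_residual[1], fit$coefficient,
                             fit$stdev_unscaled, d0 = Inf)
  expect_equal(unique(round(mInf$post_var, 12)), round(mInf$s0_2, 12))
  ## estimated d0 is positive and posterior variances sit between s2 and s02
  m <- moderate_variances(fit$s2, fit$df_residual[1])
  lo <- pmin(fit$s2, m$s0_2); hi <- pmax(fit$s2, m$s0_2)
  expect_true(all(m$post_var >= lo - 1e-12 & m$post_var <= hi + 1e-12))
  expect_gt(m$d0, 0)
})

test_that("moderated statistics agree with an independent implementation", {
  set.seed(72)
  n <- 12
  beta <- matrix(rbeta(300 * n, 4, 6), 300,
                 dimnames = list(sprintf("cg%03d", 1:300), sprintf("S%d", 1:n)))
  grp <- rep(c("case", "control"), each = n / 2)
  samples <- data.frame(sample_id = colnames(beta), group = grp,
                        age = 30, sex = "M", batch_id = "B1")
  fit <- fit_probe_models(beta, samples)
  m <- moderate_variances(fit$s2, fit$df_residual[1], fit$coefficient,
                          fit$stdev_unscaled)
  design <- model.matrix(~ grp == "case")
  lf <- limma::eBayes(limma::lmFit(beta, design))
  expect_equal(m$d0, lf$df.prior, tolerance = 1e-6)
  expect_equal(unname(m$s0_2), unname(lf$s2.prior), tolerance = 1e-6)
  expect_equal(unname(m$t), unname(lf$t[, 2]), tolerance = 1e-8)
  expect_equal(unname(m$p), unname(lf$p.value[, 2]), tolerance = 1e-8)
})

test_that("null simulation keeps the moderated-t size at its nominal level", {
  set.seed(73)
  n <- 20
  beta <- matrix(plogis(rnorm(2000 * n, 0, 0.5)), 2000,
                 dimnames = list(sprintf("cg%04d", 1:2000), sprintf("S%d", 1:n)))
  samples <- data.frame(sample_id = colnames(beta),
                        group = rep(c("case", "control"), each = n / 2),
                        age = 30, sex = "M", batch_id = "B1")
  tab <- call_dmps(beta, samples)
  expect_lt(abs(mean(tab$p < 0.05) - 0.05), 0.01)
})

test_that("BH adjustment matches the brute-force definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  set.seed(74)
  for (i in 1:60) {
    p <- round(runif(sample(1:8, 1)), 3)
    expect_equal(bh_adjust(p), bh_brute(p), tolerance = 1e-12)
  }
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("DMP selection applies both thresholds and the stated ordering", {
  tab <- data.frame(probe_id = paste0("cg", 1:5),
                    delta_beta = c(0.12, 0.05, 0.3, 0.11, 0.2),
                    fdr = c(0.05, 0.09, 0.2, 0.05, 0.5))
  sel <- select_dmps(tab)
  expect_identical(sel$probe_id, c("cg1", "cg4"))
  expect_identical(select_dmps(transform(tab, fdr = 1))$probe_id, character(0))
  expect_identical(formals(select_dmps)$fdr_max, 0.1)
  expect_identical(formals(select_dmps)$delta_min, 0.1)
})

test_that("generic two-group and correlation tests match their definitions", {
  tt <- two_group_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)
  pr <- pearson_test(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(pr$r, 0.6, tolerance = 1e-12)
  expect_equal(pearson_test(1:5, 1:5)$r, 1)
  expect_error(pearson_test(1:4, rep(2, 4)), "constant")
})

test_that("planted DMPs are strongly enriched in the selection", {
  ## With the true effect sitting exactly on the |delta| >= 0.1 cutoff,
  ## each planted probe's empirical delta clears it about half the time,
  ## so full recall is not the right bar; enrichment and ranking are.
  top_rank <- fdr_recall <- sel_recall <- numeric(3)
  for (i in 1:3) {
    g <- generate_dataset(generator_config(n_probes = 2000, n_case = 30,
                                           n_control = 30, batch_shift_sd = 0,
                                           seed = 80 + i))
    tab <- call_dmps(g$dataset$beta, g$dataset$samples)
    ord <- tab$probe_id[order(tab$fdr, -abs(tab$delta_beta))]
    top_rank[i] <- mean(g$truth$planted_probe_ids %in% ord[1:20])
    fdr_recall[i] <- mean(g$truth$planted_probe_ids %in% tab$probe_id[tab$pass_fdr])
    sel <- select_dmps(tab)
    sel_recall[i] <- mean(g$truth$planted_probe_ids %in% sel$probe_id)
    ## whatever is selected is almost entirely planted (high precision)
    if (nrow(sel)) expect_gt(mean(sel$probe_id %in% g$truth$planted_probe_ids), 0.8)
  }
  expect_gt(mean(top_rank), 0.9)     # planted probes dominate the ranking
  expect_gt(mean(fdr_recall), 0.9)   # FDR filter alone recovers nearly all
  expect_gt(mean(sel_recall), 0.3)   # joint rule: knife-edge coin flips
})
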