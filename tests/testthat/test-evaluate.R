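test_that("AUC matches hand-counted concordant pairs and handles ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.85), c(1, 1, 0, 0)), 0.75)
  expect_equal(roc_auc(c(5, 6, 1, 2), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(rep(0.4, 10), rep(c(1, 0), 5)), 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("AUC equals exhaustive pair counting on random tied instances", {
  set.seed(111)
  for (i in 1:50) {
    n <- sample(4:20, 1)
    y <- sample(c(rep(1, 2), rep(0, 2), sample(0:1, n - 4, replace = TRUE)))
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)   # plenty of ties
    expect_equal(roc_auc(s, y), auc_pairs(s, y), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(112)
  s <- rnorm(30); y <- sample(rep(c(1, 0), 15))
  a <- roc_auc(s, y)
  expect_equal(roc_auc(exp(s), y), a)
  expect_equal(roc_auc(qlogis(plogis(s)) * 3 + 2, y), a)
})

test_that("AUC agrees with pROC", {
  set.seed(113)
  s <- rnorm(40); y <- sample(rep(c(1, 0), 20))
  expect_equal(roc_auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<"))),
               tolerance = 1e-12)
})

test_that("adjustment with constant covariates reduces to the raw AUC", {
  set.seed(114)
  y <- rep(c(1, 0), each = 20)
  marker <- rnorm(40, mean = y)
  r <- adjusted_auc(marker, y, covariates = data.frame(age = rep(30, 40)),
                    n_boot = 100, seed = 1)
  expect_equal(r$auc, roc_auc(marker, y), tolerance = 1e-12)
})

test_that("logistic coefficients are recovered from simulated data", {
  set.seed(115)
  n <- 2000
  x <- rnorm(n); age <- rnorm(n)
  eta <- -0.5 + 1.2 * x + 0.4 * age
  y <- rbinom(n, 1, plogis(eta))
  r <- adjusted_auc(x, y, covariates = data.frame(age = age), n_boot = 50, seed = 1)
  expect_true(r$adjusted)
  expect_equal(unname(r$coefficients), c(-0.5, 1.2, 0.4), tolerance = 0.1)
  ## with a zero-effect covariate, adjusted AUC tracks the unadjusted one
  r0 <- adjusted_auc(x, y, covariates = data.frame(noise = rnorm(n)),
                     n_boot = 50, seed = 1)
  expect_equal(r0$auc, roc_auc(x, y), tolerance = 0.02)
})

test_that("the logistic fit matches a brute-force likelihood grid at n=8", {
  x <- c(-1.5, -1.0, -0.5, -0.2, 0.3, 0.8, 1.1, 1.6)
  y <- c(0, 0, 1, 0, 1, 0, 1, 1)
  fit <- suppressWarnings(glm(y ~ x, family = binomial()))
  grid <- expand.grid(b0 = seq(-3, 3, by = 0.05), b1 = seq(-1, 5, by = 0.05))
  ll <- mapply(logistic_loglik, grid$b0, grid$b1, MoreArgs = list(x = x, y = y))
  best <- grid[which.max(ll), ]
  expect_lt(abs(unname(coef(fit)[1]) - best$b0), 0.05)
  expect_lt(abs(unname(coef(fit)[2]) - best$b1), 0.05)
})

test_that("bootstrap intervals are ordered, deterministic, and calibrated", {
  set.seed(116)
  y <- rep(c(1, 0), each = 25)
  s <- rnorm(50, mean = y * 1.19)
  ci <- bootstrap_ci(s, y, n_boot = 400, seed = 3)
  expect_lte(ci[1], ci[2])
  expect_identical(bootstrap_ci(s, y, n_boot = 400, seed = 3), ci)
  expect_identical(formals(bootstrap_ci)$n_boot, 2000L)

  ## coverage of the true AUC (0.8) at nominal 95%
  mu <- sqrt(2) * qnorm(0.8)
  covered <- vapply(1:200, function(i) {
    set.seed(3000 + i)
    sc <- rnorm(100, mean = rep(c(mu, 0), each = 50))
    yy <- rep(c(1, 0), each = 50)
    ci <- bootstrap_ci(sc, yy, n_boot = 400, seed = i)
    ci[1] <= 0.8 && 0.8 <= ci[2]
  }, logical(1))
  expect_lt(abs(mean(covered) - 0.95), 0.05)
})

test_that("the Youden operating point matches exhaustive enumeration", {
  op <- operating_point(c(1, 0), c(1, 0))
  expect_equal(op$sensitivity, 1)
  expect_equal(op$specificity, 1)

  op2 <- operating_point(c(0.9, 0.8, 0.4, 0.3, 0.2, 0.7), c(1, 1, 1, 0, 0, 0))
  oracle <- youden_brute(c(0.9, 0.8, 0.4, 0.3, 0.2, 0.7), c(1, 1, 1, 0, 0, 0))
  expect_equal(op2$youden_j, oracle$j, tolerance = 1e-12)
  expect_equal(op2$sensitivity + op2$specificity, oracle$sens + oracle$spec)

  set.seed(117)
  for (i in 1:20) {
    n <- sample(6:16, 1)
    s <- sample(seq(0, 1, 0.05), n, replace = TRUE)
    y <- sample(c(1, 0, sample(0:1, n - 2, replace = TRUE)))
    op <- operating_point(s, y)
    expect_equal(op$youden_j, youden_brute(s, y)$j, tolerance = 1e-12)
  }

  expect_equal(operating_point(rep(0.5, 8), rep(c(1, 0), 4))$youden_j, 0)
})

test_that("clinical correlations behave at the extremes and under the null", {
  m <- rnorm(30)
  tab <- correlate_clinical(m, data.frame(same = m, anti = -m))
  expect_equal(tab$r, c(1, -1), tolerance = 1e-12)
  set.seed(118)
  ps <- vapply(1:200, function(i) {
    correlate_clinical(rnorm(50), data.frame(s = rnorm(50)))$p
  }, numeric(1))
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.04)
  expect_error(correlate_clinical(m, data.frame(k = rep(1, 30))), "constant")
})
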