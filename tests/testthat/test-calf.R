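test_that("a perfect single predictor is selected alone with weight +1", {
  y <- rep(c(1, 0), each = 10)
  x <- matrix(as.numeric(y), ncol = 1, dimnames = list(NULL, "cgA"))
  m <- greedy_fit(x, y)
  expect_identical(m$features$probe_id, "cgA")
  expect_identical(m$features$weight, 1L)
  expect_equal(m$final_metric, 1.0, tolerance = 1e-9)
  expect_identical(length(m$trajectory), 1L)
})

test_that("greedy selection properties hold on random instances", {
  set.seed(92)
  for (i in 1:20) {
    n <- 24; p <- sample(4:12, 1)
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("F%02d", 1:p)))
    y <- sample(rep(c(1, 0), each = n / 2))
    ## limit=1 equals exhaustive best signed single feature
    m1 <- greedy_fit(x, y, limit = 1)
    oracle <- calf_step1_brute(x, y)
    expect_identical(m1$features$probe_id, colnames(x)[oracle$feature])
    expect_identical(as.numeric(m1$features$weight), oracle$weight)
    expect_equal(m1$final_metric, oracle$metric, tolerance = 1e-9)
    ## trajectory strictly increasing on any accepted model
    m <- greedy_fit(x, y, limit = 10)
    expect_true(all(diff(m$trajectory) > 0))
    expect_lte(nrow(m$features), 10)
    expect_false(anyDuplicated(m$features$probe_id) > 0)
    ## greedy pair never beats the exhaustive best pair
    if (p <= 8) {
      m2 <- greedy_fit(x, y, limit = 2)
      expect_lte(m2$final_metric, calf_pair_brute(x, y) + 1e-9)
    }
  }
})

test_that("constant features are skipped with a log entry", {
  y <- rep(c(1, 0), each = 6)
  x <- cbind(flat = rep(0.5, 12), sig = as.numeric(y) + rnorm(12, 0, 0.1))
  m <- greedy_fit(x, y)
  expect_identical(m$skipped, "flat")
  expect_false("flat" %in% m$features$probe_id)
})

test_that("the permutation p has the stated floor, worst case and determinism", {
  ## uninformative single feature: observed metric 0, every permutation >= it
  y <- rep(c(1, 0), each = 4)
  x <- matrix(c(1, 1, -1, -1, 1, 1, -1, -1), ncol = 1, dimnames = list(NULL, "cgZ"))
  pr <- permutation_test(x, y, n_perm = 200, seed = 5)
  expect_equal(pr$p, 1.0)

  ## strong separation: p hits the 1/n_perm floor
  set.seed(93)
  n <- 24
  xs <- matrix(rnorm(n * 10, 0, 0.05), n, 10)
  ys <- rep(c(1, 0), each = n / 2)
  xs[ys == 1, 1:4] <- xs[ys == 1, 1:4] + 0.5
  pr2 <- permutation_test(xs, ys, n_perm = 500, seed = 7)
  expect_equal(pr2$p, 1 / 500)
  expect_identical(pr2$p, max(sum(pr2$permuted >= pr2$observed), 1) / 500)

  ## bit-for-bit reproducible given the seed; add-one estimator agrees
  pr3 <- permutation_test(xs, ys, n_perm = 500, seed = 7)
  expect_identical(pr2$permuted, pr3$permuted)
  pr4 <- permutation_test(xs, ys, n_perm = 500, seed = 7, estimator = "add_one")
  expect_equal(pr4$p, (sum(pr4$permuted >= pr4$observed) + 1) / 501)

  expect_warning(permutation_test(xs, ys, n_perm = 50, seed = 1), "resolution")
})

test_that("stability selection counts a dominant marker in nearly every trial", {
  set.seed(94)
  n1 <- 20; n0 <- 30
  y <- c(rep(1, n1), rep(0, n0))
  x <- matrix(rnorm((n1 + n0) * 50, 0, 0.03), n1 + n0, 50,
              dimnames = list(NULL, sprintf("cg%02d", 1:50)))
  x[y == 1, 1] <- x[y == 1, 1] + 0.15
  st <- stability_selection(x, y, n_trials = 300, seed = 9)
  expect_gte(st$counts[["cg01"]], 285)            # >= 95% of trials
  expect_true(all(st$counts <= st$n_trials))
  expect_lte(sum(st$counts), st$n_trials * 10)
  ## deterministic given seed
  st2 <- stability_selection(x, y, n_trials = 300, seed = 9)
  expect_identical(st$counts, st2$counts)
  expect_error(stability_selection(x, y, fraction = 1.5), "fraction")
})

test_that("consensus markers follow the stated set logic and ordering", {
  fm <- structure(list(features = data.frame(
    probe_id = c("b", "c", "d"), weight = c(1L, -1L, 1L))), class = "calf_model")
  st <- structure(list(counts = c(a = 1900L, b = 1800L, c = 900L, d = 100L),
                       n_trials = 2000L, min_count = 750L), class = "stability_result")
  cm <- consensus_markers(fm, st)
  expect_identical(cm$probe_id, c("b", "c"))
  expect_identical(cm$stability_count, c(1800L, 900L))
  ## empty stable set
  st$counts[] <- 0L
  expect_identical(nrow(consensus_markers(fm, st)), 0L)
  ## identical sets come back in count order
  st$counts <- c(a = 0L, b = 800L, c = 1200L, d = 900L)
  expect_identical(consensus_markers(fm, st)$probe_id, c("c", "d", "b"))
})
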