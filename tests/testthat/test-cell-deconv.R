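test_that("a pure cell-type profile is recovered as a unit vector", {
  ref <- ref_fixture()
  w <- matrix(0, 2, 6, dimnames = list(NULL, colnames(ref)))
  w[1, "Gran"] <- 1
  w[2, "CD4T"] <- 1
  props <- estimate_proportions(mix_dataset(ref, w), ref)
  expect_equal(unname(props$proportions[1, ]), c(0, 0, 0, 0, 0, 1), tolerance = 1e-9)
  expect_equal(unname(props$proportions[2, ]), c(0, 0, 1, 0, 0, 0), tolerance = 1e-9)
})

test_that("a noiseless mixture is recovered to numerical precision", {
  ref <- ref_fixture()
  w <- matrix(c(0.3, 0, 0.5, 0.2, 0, 0), 1, 6,
              dimnames = list(NULL, colnames(ref)))   # B 0.3, CD4T 0.5, NK 0.2
  props <- estimate_proportions(mix_dataset(ref, w), ref)
  expect_equal(unname(props$proportions[1, ]), as.vector(w), tolerance = 1e-6)
  expect_lt(props$residual_norm[1], 1e-8)
})

test_that("noisy mixtures are recovered within 0.05 per proportion", {
  set.seed(62)
  ref <- ref_fixture()
  w <- matrix(rgamma(100 * 6, c(3, 5, 8, 3, 4, 27)), 100, 6, byrow = TRUE)
  w <- w / rowSums(w)
  colnames(w) <- colnames(ref)
  props <- estimate_proportions(mix_dataset(ref, w, noise_sd = 0.02), ref)
  err <- abs(props$proportions - w)
  expect_lt(max(err), 0.05)
  expect_lt(mean(err), 0.02)
  expect_equal(unname(rowSums(props$proportions)), rep(1, 100), tolerance = 1e-9)
})

test_that("adding a true component never increases the projection residual", {
  set.seed(63)
  ref <- ref_fixture()
  w <- matrix(c(0.4, 0.3, 0.3, 0, 0, 0), 1, 6, dimnames = list(NULL, colnames(ref)))
  ds <- mix_dataset(ref, w, noise_sd = 0.02)
  full <- estimate_proportions(ds, ref)$residual_norm[1]
  ## cripple the reference: replace the truly-present CD4T profile with a
  ## flat profile; restoring the true component must not raise the residual
  crippled <- ref
  crippled[, "CD4T"] <- 0.5
  part <- suppressWarnings(estimate_proportions(ds, crippled))$residual_norm[1]
  expect_lte(full, part + 1e-12)
})

test_that("estimates are equivariant under sample reordering", {
  set.seed(64)
  ref <- ref_fixture()
  w <- matrix(rgamma(8 * 6, 2), 8, 6); w <- w / rowSums(w); colnames(w) <- colnames(ref)
  ds <- mix_dataset(ref, w, noise_sd = 0.02)
  p1 <- estimate_proportions(ds, ref)$proportions
  perm <- sample(8)
  ds2 <- ds
  ds2$beta <- ds2$beta[, perm]; ds2$detection_p <- ds2$detection_p[, perm]
  ds2$bead_count <- ds2$bead_count[, perm]; ds2$samples <- ds2$samples[perm, ]
  p2 <- estimate_proportions(ds2, ref)$proportions
  expect_equal(p2, p1[perm, ])
})

test_that("insufficient probe overlap is an error", {
  ref <- ref_fixture()
  ds <- mix_dataset(ref, matrix(rep(1 / 6, 6), 1, 6, dimnames = list(NULL, colnames(ref))))
  big_ref <- rbind(ref, ref, ref)
  rownames(big_ref) <- sprintf("cg%08d", 1:nrow(big_ref) + 1000)
  expect_error(estimate_proportions(ds, big_ref), "50%")
})

test_that("composition comparison behaves under null, identity and shift", {
  set.seed(65)
  ref <- ref_fixture()
  ## identical per-group proportions: t = 0, p = 1
  w0 <- matrix(rep(c(0.1, 0.1, 0.2, 0.1, 0.1, 0.4), each = 8), 8, 6)
  colnames(w0) <- colnames(ref)
  ds0 <- mix_dataset(ref, w0)
  tab0 <- compare_composition(estimate_proportions(ds0, ref), ds0$samples)
  expect_equal(tab0$t, rep(0, 6), tolerance = 1e-6)
  expect_equal(tab0$p, rep(1, 6), tolerance = 1e-6)

  ## null calibration: ~5% of cell-type tests reject at 0.05
  reject <- logical(0)
  for (rep_i in 1:200) {
    w <- matrix(rgamma(20 * 6, c(3, 5, 8, 3, 4, 27)), 20, 6, byrow = TRUE)
    w <- w / rowSums(w)
    grp <- rep(c("case", "control"), each = 10)
    ps <- vapply(1:6, function(k) {
      two_group_test(w[grp == "case", k], w[grp == "control", k])$p
    }, numeric(1))
    reject <- c(reject, ps < 0.05)
  }
  expect_lt(abs(mean(reject) - 0.05), 0.03)

  ## a planted monocyte shift is detected
  w1 <- matrix(rgamma(60 * 6, c(3, 5, 8, 3, 4, 27)), 60, 6, byrow = TRUE)
  w1 <- w1 / rowSums(w1)
  grp <- rep(c("case", "control"), each = 30)
  w1[grp == "case", 5] <- w1[grp == "case", 5] + 0.10
  w1 <- w1 / rowSums(w1)
  colnames(w1) <- colnames(ref)
  ds1 <- mix_dataset(ref, w1, noise_sd = 0.01)
  ds1$samples$group <- grp
  tab1 <- compare_composition(estimate_proportions(ds1, ref), ds1$samples)
  expect_lt(tab1$p[tab1$cell_type == "Mono"], 0.01)
})
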