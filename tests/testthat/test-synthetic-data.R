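test_that("generation is deterministic given the config seed", {
  cfg <- generator_config(n_probes = 300, n_case = 8, n_control = 8, seed = 42)
  g1 <- generate_dataset(cfg)
  g2 <- generate_dataset(cfg)
  expect_identical(g1$dataset, g2$dataset)
  expect_identical(g1$truth$planted_probe_ids, g2$truth$planted_probe_ids)
})

test_that("without planted effects the group difference is null everywhere", {
  cfg <- generator_config(n_probes = 500, n_case = 200, n_control = 200,
                          planted_dmp_count = 0, batch_shift_sd = 0,
                          noise_sd = 0.10,
                          dirichlet_alpha = 4 * c(3, 5, 8, 3, 4, 27),
                          seed = 7)
  g <- generate_dataset(cfg)
  grp <- g$dataset$samples$group == "case"
  d <- rowMeans(g$dataset$beta[, grp]) - rowMeans(g$dataset$beta[, !grp])
  expect_lt(max(abs(d)), 0.01)
})

test_that("planted probes carry the configured beta difference", {
  cfg <- generator_config(n_probes = 1000, n_case = 200, n_control = 200,
                          delta_beta = 0.10, seed = 3)
  g <- generate_dataset(cfg)
  grp <- g$dataset$samples$group == "case"
  d <- rowMeans(g$dataset$beta[g$truth$planted_probe_ids, grp]) -
    rowMeans(g$dataset$beta[g$truth$planted_probe_ids, !grp])
  expect_lt(abs(mean(d) - 0.10), 0.01)
  expect_identical(unname(g$truth$delta_beta), rep(0.10, 10))
})

test_that("default clinical means match the cohort profile", {
  cfg <- generator_config()
  expect_equal(cfg$clinical_means$ados, c(case = 7.0, control = 1.5))
  expect_equal(cfg$clinical_means$assq, c(case = 28.6, control = 6.1))
})

test_that("cell proportions are Dirichlet draws summing to one", {
  g <- generate_dataset(generator_config(n_probes = 200, n_case = 50,
                                         n_control = 50, seed = 5))
  w <- g$truth$cell_props
  expect_equal(unname(rowSums(w)), rep(1, nrow(w)), tolerance = 1e-9)
  expect_true(all(w >= 0))
  a <- g$truth$config$dirichlet_alpha
  expect_equal(unname(colMeans(w)), unname(a / sum(a)), tolerance = 0.05)
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(generator_config(n_probes = 0), "n_probes")
  expect_error(generator_config(delta_beta = 1.5), "delta_beta")
  expect_error(generator_config(failure_rate_detection = -0.1), "failure_rate_detection")
  expect_error(generator_config(dirichlet_alpha = c(1, 2, 3)), "dirichlet_alpha")
  expect_error(generator_config(n_probes = 10, planted_dmp_count = 20),
               "planted_dmp_count")
})

test_that("write/read round trip is lossless and validated", {
  g <- generate_dataset(generator_config(n_probes = 120, n_case = 5,
                                         n_control = 5, seed = 9))
  dir <- withr::local_tempdir()
  write_dataset(g$dataset, dir, truth = g$truth)
  back <- read_dataset(dir)
  expect_equal(back$beta, g$dataset$beta, tolerance = 1e-6)
  expect_identical(back$annotation, g$dataset$annotation)
  expect_identical(back$samples, g$dataset$samples)
  expect_identical(back$bead_count, g$dataset$bead_count)

  ## missing mandatory sample-sheet column
  bad <- withr::local_tempdir()
  write_dataset(g$dataset, bad)
  sm <- data.table::fread(file.path(bad, "samples.tsv"))
  sm$group <- NULL
  data.table::fwrite(sm, file.path(bad, "samples.tsv"), sep = "\t")
  expect_error(read_dataset(bad), "group")

  ## out-of-range beta is rejected with probe and sample named
  bad2 <- withr::local_tempdir()
  write_dataset(g$dataset, bad2)
  bt <- data.table::fread(file.path(bad2, "beta.tsv"))
  bt[[2]][3] <- 1.2
  data.table::fwrite(bt, file.path(bad2, "beta.tsv"), sep = "\t")
  expect_error(read_dataset(bad2), "out of \\[0,1\\].*cg00000003")
})

test_that("identical configs give byte-identical files on disk", {
  g <- generate_dataset(generator_config(n_probes = 100, n_case = 4,
                                         n_control = 4, seed = 1))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(g$dataset, d1, truth = g$truth)
  write_dataset(g$dataset, d2, truth = g$truth)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})
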