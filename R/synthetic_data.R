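#' Configuration for the synthetic 450K-like dataset generator
#'
#' Builds and validates the full parameter set for [generate_dataset()].
#' Defaults emulate a small adult case/control blood methylation study:
#' two groups with a handful of planted differentially methylated
#' positions at a case-minus-control beta difference of 0.10, per-sample
#' leukocyte mixtures over six reference cell types drawn from a
#' blood-like Dirichlet, batch location/scale effects on the logit
#' scale, probe-type-dependent dynamic range (type-II compression), and
#' sporadic detection/bead-count failures. Clinical severity scores
#' default to the group means of the motivating cohort (ADOS 7.0 vs
#' 1.5; ASSQ-R 28.6 vs 6.1; matched IQ).
#'
#' @param n_probes number of CpG probes.
#' @param n_case,n_control samples per group.
#' @param planted_dmp_count number of probes carrying a true group effect.
#' @param delta_beta true case-minus-control beta difference at planted
#'   probes (beta units).
#' @param noise_sd sd of probe-level Gaussian noise on the logit scale.
#' @param dirichlet_alpha positive 6-vector of Dirichlet concentrations
#'   for per-sample cell proportions (B, CD8T, CD4T, NK, Mono, Gran).
#' @param batch_count number of array batches.
#' @param batch_shift_sd sd of per-batch additive shifts (logit scale).
#' @param batch_scale_sd sd of log per-batch noise scale factors.
#' @param failure_rate_detection per-entry probability of a detection
#'   p-value failure (p > 0.01).
#' @param failure_rate_beads per-entry probability of a low bead count (< 3).
#' @param clinical_means list with `ados`, `assq`, `iq`, each a
#'   2-vector `c(case=, control=)` of group means.
#' @param prop_sex,prop_snp,prop_cross_reactive proportions of probes on
#'   sex chromosomes, SNP-flagged, and cross-reactive.
#' @param cell_probe_count number of cell-type discriminating probes
#'   (these define the deconvolution reference; never planted).
#' @param type2_fraction fraction of probes assayed with type-II chemistry.
#' @param type2_attenuation compression of type-II betas toward 0.5
#'   (1 = none); gives BMIQ a real distortion to correct.
#' @param seed integer RNG seed.
#' @return a validated `generator_config` list.
#' @export
generator_config <- function(n_probes = 2000L,
                             n_case = 30L,
                             n_control = 30L,
                             planted_dmp_count = 10L,
                             delta_beta = 0.10,
                             noise_sd = 0.15,
                             dirichlet_alpha = c(B = 3, CD8T = 5, CD4T = 8,
                                                 NK = 3, Mono = 4, Gran = 27),
                             batch_count = 2L,
                             batch_shift_sd = 0.2,
                             batch_scale_sd = 0.05,
                             failure_rate_detection = 0.002,
                             failure_rate_beads = 0.01,
                             clinical_means = list(
                               ados = c(case = 7.0, control = 1.5),
                               assq = c(case = 28.6, control = 6.1),
                               iq = c(case = 110, control = 110)),
                             prop_sex = 0.03,
                             prop_snp = 0.03,
                             prop_cross_reactive = 0.03,
                             cell_probe_count = 120L,
                             type2_fraction = 0.7,
                             type2_attenuation = 0.75,
                             seed = 1L) {
  cfg <- list(
    n_probes = check_count(n_probes, "n_probes"),
    n_case = check_count(n_case, "n_case"),
    n_control = check_count(n_control, "n_control"),
    planted_dmp_count = check_count(planted_dmp_count, "planted_dmp_count", min = 0),
    delta_beta = check_prob(delta_beta, "delta_beta"),
    noise_sd = check_nonneg(noise_sd, "noise_sd"),
    dirichlet_alpha = dirichlet_alpha,
    batch_count = check_count(batch_count, "batch_count"),
    batch_shift_sd = check_nonneg(batch_shift_sd, "batch_shift_sd"),
    batch_scale_sd = check_nonneg(batch_scale_sd, "batch_scale_sd"),
    failure_rate_detection = check_prob(failure_rate_detection, "failure_rate_detection"),
    failure_rate_beads = check_prob(failure_rate_beads, "failure_rate_beads"),
    clinical_means = clinical_means,
    prop_sex = check_prob(prop_sex, "prop_sex"),
    prop_snp = check_prob(prop_snp, "prop_snp"),
    prop_cross_reactive = check_prob(prop_cross_reactive, "prop_cross_reactive"),
    cell_probe_count = check_count(cell_probe_count, "cell_probe_count", min = 0),
    type2_fraction = check_prob(type2_fraction, "type2_fraction"),
    type2_attenuation = check_prob(type2_attenuation, "type2_attenuation"),
    seed = check_count(seed, "seed", min = 0)
  )
  if (length(cfg$dirichlet_alpha) != 6L || any(!is.finite(cfg$dirichlet_alpha)) ||
      any(cfg$dirichlet_alpha <= 0))
    stop_config("dirichlet_alpha", "must be a strictly positive 6-vector")
  if (cfg$planted_dmp_count > cfg$n_probes)
    stop_config("planted_dmp_count", "must not exceed n_probes")
  for (nm in c("ados", "assq", "iq")) {
    v <- cfg$clinical_means[[nm]]
    if (is.null(v) || length(v) != 2L || !is.numeric(v))
      stop_config("clinical_means", sprintf("must contain a numeric 2-vector '%s'", nm))
  }
  structure(cfg, class = "generator_config")
}

CELL_TYPES <- c("B", "CD8T", "CD4T", "NK", "Mono", "Gran")

#' Generate a synthetic 450K-like methylation dataset with ground truth
#'
#' Betas arise by mixing six latent per-cell-type probe profiles with
#' per-sample Dirichlet cell proportions (mixing in beta space, since a
#' beta value is a molecule fraction), compressing type-II probes toward
#' 0.5, adding the planted case effect, then applying per-batch
#' location/scale perturbations and Gaussian probe noise on the logit
#' scale and mapping back through the inverse logit. Values are clipped
#' to `[1e-6, 1 - 1e-6]`. Detection p-value and bead-count failures are
#' planted entry-wise at the configured rates.
#'
#' @param config a [generator_config()].
#' @return list with elements `dataset` (a `methyl_dataset`) and `truth`
#'   (planted probe ids and effects, per-batch shift/scale, true cell
#'   proportions, and the latent cell-type reference profile matrix).
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "generator_config")) config <- do.call(generator_config, config)
  set.seed(config$seed)
  np <- config$n_probes
  n <- config$n_case + config$n_control

  probe_id <- sprintf("cg%08d", seq_len(np))
  n_sex <- round(config$prop_sex * np)
  chromosome <- sample(as.character(1:22), np, replace = TRUE)
  sex_idx <- if (n_sex > 0) sample.int(np, n_sex) else integer(0)
  chromosome[sex_idx] <- sample(c("X", "Y"), length(sex_idx), replace = TRUE, prob = c(0.9, 0.1))
  snp_flag <- as.integer(runif(np) < config$prop_snp)
  cross_reactive_flag <- as.integer(runif(np) < config$prop_cross_reactive)
  design_type <- ifelse(runif(np) < config$type2_fraction, "II", "I")
  gene_symbol <- sprintf("GENE%05d", sample.int(max(np %/% 3, 1), np, replace = TRUE))
  annotation <- data.frame(probe_id = probe_id, chromosome = chromosome,
                           design_type = design_type, snp_flag = snp_flag,
                           cross_reactive_flag = cross_reactive_flag,
                           gene_symbol = gene_symbol, stringsAsFactors = FALSE)

  clean <- which(!(chromosome %in% c("X", "Y")) & snp_flag == 0L & cross_reactive_flag == 0L)
  ncell <- min(config$cell_probe_count, length(clean))
  cell_idx <- if (ncell > 0) sort(sample(clean, ncell)) else integer(0)
  plantable <- setdiff(clean, cell_idx)
  nplant <- min(config$planted_dmp_count, length(plantable))
  planted_idx <- if (nplant > 0) sort(sample(plantable, nplant)) else integer(0)

  ## bimodal 450K-like base profile; planted probes mid-range so the
  ## added effect stays inside [0,1]
  comp <- sample.int(3L, np, replace = TRUE, prob = c(0.42, 0.38, 0.20))
  base <- numeric(np)
  base[comp == 1L] <- rbeta(sum(comp == 1L), 1.5, 18)
  base[comp == 2L] <- rbeta(sum(comp == 2L), 18, 1.5)
  base[comp == 3L] <- rbeta(sum(comp == 3L), 8, 8)
  base[planted_idx] <- runif(length(planted_idx), 0.30, 0.55)
  base <- clip_beta(base)

  ## latent cell-type profiles: identical except at discriminating
  ## probes, each hypermethylated in exactly one cell type
  profiles <- matrix(base, nrow = np, ncol = 6,
                     dimnames = list(probe_id, CELL_TYPES))
  if (ncell > 0) {
    owner <- rep_len(seq_len(6L), ncell)
    for (j in seq_along(cell_idx)) {
      profiles[cell_idx[j], ] <- clip_beta(rnorm(6, 0.12, 0.02))
      profiles[cell_idx[j], owner[j]] <- clip_beta(rnorm(1, 0.85, 0.02))
    }
  }

  group <- c(rep("case", config$n_case), rep("control", config$n_control))
  sample_id <- sprintf("S%04d", seq_len(n))
  batch_id <- unlist(lapply(c(config$n_case, config$n_control), function(m)
    sample(rep_len(seq_len(config$batch_count), m))), use.names = FALSE)
  cm <- config$clinical_means
  mk_clin <- function(means, sds, lower, upper = Inf) {
    ifelse(group == "case",
           rnorm_trunc(n, means[["case"]], sds[1], lower, upper),
           rnorm_trunc(n, means[["control"]], sds[2], lower, upper))
  }
  samples <- data.frame(
    sample_id = sample_id, group = group,
    age = round(rnorm_trunc(n, 27, 6, 18, 50), 1),
    sex = ifelse(runif(n) < 0.8, "M", "F"),
    batch_id = sprintf("B%d", batch_id),
    iq = round(mk_clin(cm$iq, c(10, 10), 80, 145)),
    ados_total = round(mk_clin(cm$ados, c(2.5, 1.2), 0), 1),
    assq_total = round(mk_clin(cm$assq, c(8, 4), 0), 1),
    stringsAsFactors = FALSE)

  w <- rdirichlet(n, config$dirichlet_alpha)
  colnames(w) <- CELL_TYPES
  rownames(w) <- sample_id

  m <- profiles %*% t(w)                      # beta-space cell mixing
  t2 <- design_type == "II"
  m[t2, ] <- 0.5 + config$type2_attenuation * (m[t2, ] - 0.5)
  if (length(planted_idx))
    m[planted_idx, group == "case"] <- m[planted_idx, group == "case"] + config$delta_beta
  m <- clip_beta(m)

  shift <- rnorm(config$batch_count, 0, config$batch_shift_sd)
  scale <- exp(rnorm(config$batch_count, 0, config$batch_scale_sd))
  l <- logit(m)
  eps <- matrix(rnorm(np * n, 0, config$noise_sd), np, n)
  l <- l + rep(shift[batch_id], each = np) + eps * rep(scale[batch_id], each = np)
  beta <- clip_beta(inv_logit(l))
  dimnames(beta) <- list(probe_id, sample_id)

  detection_p <- matrix(runif(np * n, 0, 0.005), np, n, dimnames = dimnames(beta))
  fail_d <- runif(np * n) < config$failure_rate_detection
  detection_p[fail_d] <- runif(sum(fail_d), 0.011, 0.8)
  bead_count <- matrix(3L + rpois(np * n, 12), np, n, dimnames = dimnames(beta))
  fail_b <- runif(np * n) < config$failure_rate_beads
  bead_count[fail_b] <- sample(0:2, sum(fail_b), replace = TRUE)

  dataset <- methyl_dataset(beta, detection_p, bead_count, annotation, samples)
  truth <- structure(list(
    planted_probe_ids = probe_id[planted_idx],
    delta_beta = setNames(rep(config$delta_beta, length(planted_idx)), probe_id[planted_idx]),
    batch_shift = setNames(shift, sprintf("B%d", seq_len(config$batch_count))),
    batch_scale = setNames(scale, sprintf("B%d", seq_len(config$batch_count))),
    cell_props = w,
    cell_reference = profiles[cell_idx, , drop = FALSE],
    config = unclass(config)
  ), class = "truth_record")
  list(dataset = dataset, truth = truth)
}

#' Construct and validate a methylation dataset container
#'
#' @param beta probes x samples matrix of betas in `[0, 1]`.
#' @param detection_p matrix of detection p-values, same shape.
#' @param bead_count matrix of nonnegative integer bead counts, same shape.
#' @param annotation data.frame with columns probe_id, chromosome,
#'   design_type, snp_flag, cross_reactive_flag and optionally gene_symbol.
#' @param samples data.frame with columns sample_id, group, age, sex,
#'   batch_id, iq, ados_total, assq_total.
#' @return a `methyl_dataset` object.
#' @export
methyl_dataset <- function(beta, detection_p, bead_count, annotation, samples) {
  x <- structure(list(beta = beta, detection_p = detection_p,
                      bead_count = bead_count, annotation = annotation,
                      samples = samples), class = "methyl_dataset")
  validate_methyl_dataset(x)
  x
}

#' @export
print.methyl_dataset <- function(x, ...) {
  cat(sprintf("methyl_dataset: %d probes x %d samples (%d case / %d control)\n",
              nrow(x$beta), ncol(x$beta),
              sum(x$samples$group == "case"), sum(x$samples$group == "control")))
  invisible(x)
}

validate_methyl_dataset <- function(x) {
  stopifnot(inherits(x, "methyl_dataset"))
  dims <- dim(x$beta)
  if (!identical(dim(x$detection_p), dims) || !identical(dim(x$bead_count), dims))
    stop("methyl_dataset: matrix dimensions disagree", call. = FALSE)
  if (nrow(x$annotation) != dims[1])
    stop("methyl_dataset: annotation rows do not match probe count", call. = FALSE)
  if (nrow(x$samples) != dims[2])
    stop("methyl_dataset: sample sheet rows do not match sample count", call. = FALSE)
  if (anyDuplicated(x$annotation$probe_id))
    stop("methyl_dataset: duplicated probe_id", call. = FALSE)
  if (anyDuplicated(x$samples$sample_id))
    stop("methyl_dataset: duplicated sample_id", call. = FALSE)
  if (any(x$beta < 0 | x$beta > 1, na.rm = FALSE))
    stop("methyl_dataset: beta values outside [0, 1]", call. = FALSE)
  if (any(x$bead_count < 0))
    stop("methyl_dataset: negative bead counts", call. = FALSE)
  req <- c("sample_id", "group", "age", "sex", "batch_id")
  miss <- setdiff(req, names(x$samples))
  if (length(miss))
    stop(sprintf("methyl_dataset: sample sheet missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}
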