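#' Full discovery-pipeline configuration
#'
#' Bundles every stage's settings. Numeric defaults are the study
#' settings of the motivating analysis: DMP thresholds FDR <= 0.1 and
#' |delta beta| >= 0.1; CALF limit 10, 2000 permutations, 2000
#' stability trials at 80% class-stratified subsampling with a
#' 750-trial consensus threshold; 500-tree forest with tuned mtry;
#' 2000 bootstrap replications for the AUC CI.
#'
#' @param generator a [generator_config()] describing the synthetic
#'   input, or NULL when `input_dir` is given.
#' @param input_dir directory with an on-disk dataset (see
#'   [read_dataset()]); overrides `generator`.
#' @param reference_file optional TSV cell-type reference; when
#'   generating, the generator's latent profiles are used.
#' @param thresholds a [filter_thresholds()].
#' @param batch_variables sample-sheet columns adjusted sequentially
#'   (default sex then array batch).
#' @param deconv run cell-type deconvolution (default TRUE).
#' @param fdr_max,delta_min DMP selection thresholds.
#' @param max_candidates cap on candidate markers carried into the
#'   machine-learning stage (top rows by FDR; default 50).
#' @param calf_limit,n_perm,n_trials,fraction,min_count CALF settings.
#' @param ntree,mtry forest settings.
#' @param n_boot bootstrap replications for ROC CIs.
#' @param covariates adjustment covariates for the final ROC model.
#' @param seed global seed; per-stage seeds are derived from it by
#'   stage-name hashing ([derive_seed()]).
#' @param out_dir output directory for the report bundle.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(generator = generator_config(),
                            input_dir = NULL,
                            reference_file = NULL,
                            thresholds = filter_thresholds(),
                            batch_variables = c("sex", "batch_id"),
                            deconv = TRUE,
                            fdr_max = 0.1, delta_min = 0.1,
                            max_candidates = 50L,
                            calf_limit = 10L, n_perm = 2000L,
                            n_trials = 2000L, fraction = 0.8, min_count = 750L,
                            ntree = 500L, mtry = "tune",
                            n_boot = 2000L,
                            covariates = c("age", "sex"),
                            seed = 1L,
                            out_dir = tempfile("methmark_run_")) {
  structure(list(generator = generator, input_dir = input_dir,
                 reference_file = reference_file, thresholds = thresholds,
                 batch_variables = batch_variables, deconv = isTRUE(deconv),
                 fdr_max = fdr_max, delta_min = delta_min,
                 max_candidates = as.integer(max_candidates),
                 calf_limit = as.integer(calf_limit),
                 n_perm = as.integer(n_perm), n_trials = as.integer(n_trials),
                 fraction = fraction, min_count = as.integer(min_count),
                 ntree = as.integer(ntree), mtry = mtry,
                 n_boot = as.integer(n_boot), covariates = covariates,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full biomarker-discovery pipeline
#'
#' Stage order: probe QC -> BMIQ -> batch adjustment -> cell-type
#' deconvolution -> moderated-t DMP calling -> random-forest importance
#' and CALF selection (permutation + stability + consensus) -> ROC
#' evaluation of the top consensus marker with covariate adjustment,
#' bootstrap CI, Youden operating point, and clinical correlations.
#' Every artifact is written under `config$out_dir`; a rerun with the
#' identical config is byte-identical. A stage failure aborts with the
#' stage named and leaves a `FAILED` marker next to any partial output.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the report bundle (named list of all stage results).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                 file.path(config$out_dir, "FAILED"))
      stop(sprintf("pipeline stage '%s': %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  logf <- file.path(config$out_dir, "pipeline.log")
  loglines <- character(0)
  note <- function(...) loglines <<- c(loglines, sprintf(...))
  out <- list(config = config)

  ## --- input -------------------------------------------------------
  truth <- NULL
  ds <- stage("input", {
    if (!is.null(config$input_dir)) {
      note("input: reading dataset from %s", config$input_dir)
      read_dataset(config$input_dir)
    } else {
      gen <- config$generator
      note("input: generating synthetic dataset (seed %d)", gen$seed)
      g <- generate_dataset(gen)
      truth <- g$truth
      g$dataset
    }
  })
  note("input: %d probes x %d samples", nrow(ds$beta), ncol(ds$beta))

  ## --- QC filtering ------------------------------------------------
  fl <- stage("filter", filter_probes(ds, config$thresholds))
  out$filter_report <- fl$report
  write_filter_report(fl$report, file.path(config$out_dir, "filter_report.tsv"))
  note("filter: retained %d of %d probes", fl$report$retained, fl$report$input)
  ds <- fl$dataset

  ## --- BMIQ --------------------------------------------------------
  ds <- stage("bmiq", bmiq_normalize(ds))
  note("bmiq: normalized type-II probes in %d samples", ncol(ds$beta))

  ## --- batch adjustment -------------------------------------------
  ds <- stage("batch", batch_adjust(ds, config$batch_variables, protect = "group"))
  note("batch: adjusted for %s", paste(config$batch_variables, collapse = ", "))

  ## --- cell-type deconvolution ------------------------------------
  if (config$deconv) {
    ref <- stage("deconv", {
      if (!is.null(config$reference_file)) read_cell_reference(config$reference_file)
      else if (!is.null(truth)) truth$cell_reference
      else stop("no cell-type reference available: supply reference_file")
    })
    props <- stage("deconv", estimate_proportions(ds, ref))
    out$cell_props <- props
    data.table::fwrite(cbind(data.frame(sample_id = rownames(props$proportions)),
                             as.data.frame(round(props$proportions, 6))),
                       file.path(config$out_dir, "cell_props.tsv"), sep = "\t")
    comp <- stage("deconv", compare_composition(props, ds$samples))
    out$composition_tests <- comp
    data.table::fwrite(comp, file.path(config$out_dir, "composition_tests.tsv"), sep = "\t")
    note("deconv: min composition-test p = %.3g", min(comp$p))
  }

  ## --- DMP calling -------------------------------------------------
  dmps <- stage("dmp", call_dmps(ds$beta, ds$samples, design_spec(),
                                 fdr_max = config$fdr_max, delta_min = config$delta_min))
  out$dmp_table <- dmps
  data.table::fwrite(format_num_df(dmps), file.path(config$out_dir, "dmp_table.tsv"),
                     sep = "\t")
  sel <- select_dmps(dmps, config$fdr_max, config$delta_min)
  note("dmp: %d probes pass FDR <= %.3g and |delta beta| >= %.3g",
       nrow(sel), config$fdr_max, config$delta_min)
  if (nrow(sel) < 2L) {
    ord <- dmps[order(dmps$fdr, -abs(dmps$delta_beta), dmps$probe_id), ]
    sel <- head(ord, config$max_candidates)
    note("dmp: too few passing probes; falling back to top %d by FDR", nrow(sel))
  } else if (nrow(sel) > config$max_candidates) {
    sel <- head(sel, config$max_candidates)
    note("dmp: candidate set capped at %d probes", config$max_candidates)
  }
  out$selected_dmps <- sel
  data.table::fwrite(format_num_df(sel), file.path(config$out_dir, "selected_dmps.tsv"),
                     sep = "\t")

  xsel <- t(ds$beta[sel$probe_id, , drop = FALSE])
  y <- ds$samples$group

  ## --- random forest ----------------------------------------------
  fc <- forest_config(ntree = config$ntree, mtry = config$mtry,
                      seed = derive_seed(config$seed, "forest"))
  fi <- stage("forest", grow_forest(xsel, y, fc))
  out$forest <- fi
  ranking <- rank_importance(fi, top_k = 15L)
  out$mdg_ranking <- ranking
  data.table::fwrite(format_num_df(ranking), file.path(config$out_dir, "mdg_ranking.tsv"),
                     sep = "\t")
  note("forest: mtry %d, OOB error %.3f, top MDG marker %s",
       fi$mtry, fi$oob_error, ranking$probe_id[1])

  ## --- CALF --------------------------------------------------------
  calf <- stage("calf", greedy_fit(xsel, y, limit = config$calf_limit))
  perm <- stage("calf", permutation_test(xsel, y, limit = config$calf_limit,
                                         n_perm = config$n_perm,
                                         seed = derive_seed(config$seed, "calf_perm")))
  stab <- stage("calf", stability_selection(xsel, y, limit = config$calf_limit,
                                            n_trials = config$n_trials,
                                            fraction = config$fraction,
                                            min_count = config$min_count,
                                            seed = derive_seed(config$seed, "calf_stab")))
  cons <- consensus_markers(calf, stab, min_count = config$min_count)
  out$calf <- calf; out$permutation <- perm; out$stability <- stab; out$consensus <- cons
  jsonlite::write_json(list(
    features = calf$features, metric = calf$metric,
    trajectory = round(calf$trajectory, 10),
    final_metric = round(calf$final_metric, 10),
    empirical_p = perm$p, n_perm = perm$n_perm
  ), file.path(config$out_dir, "calf_model.json"), auto_unbox = TRUE, digits = 10)
  data.table::fwrite(data.frame(probe_id = names(stab$counts),
                                count = unname(stab$counts),
                                stable = unname(stab$counts >= config$min_count)),
                     file.path(config$out_dir, "stability_counts.tsv"), sep = "\t")
  data.table::fwrite(cons, file.path(config$out_dir, "consensus_markers.tsv"), sep = "\t")
  note("calf: %d features, final metric %.4f, empirical p = %.2e; %d consensus marker(s)",
       nrow(calf$features), calf$final_metric, perm$p, nrow(cons))

  ## --- top marker evaluation ---------------------------------------
  top <- if (nrow(cons)) cons$probe_id[1] else calf$features$probe_id[1]
  if (!nrow(cons)) note("consensus empty; evaluating first full-model feature")
  marker <- ds$beta[top, ]
  cov <- ds$samples[, intersect(config$covariates, names(ds$samples)), drop = FALSE]
  roc <- stage("evaluate", adjusted_auc(marker, y, covariates = cov,
                                        n_boot = config$n_boot,
                                        seed = derive_seed(config$seed, "evaluate")))
  out$top_marker <- top
  out$roc <- roc
  data.table::fwrite(data.frame(marker = top, auc = roc$auc, ci_low = roc$ci_low,
                                ci_high = roc$ci_high, threshold = roc$threshold,
                                sensitivity = roc$sensitivity,
                                specificity = roc$specificity,
                                adjusted = roc$adjusted),
                     file.path(config$out_dir, "roc_report.tsv"), sep = "\t")
  clin_cols <- intersect(c("assq_total", "ados_total", "iq"), names(ds$samples))
  if (length(clin_cols)) {
    clin <- stage("evaluate", correlate_clinical(marker, ds$samples[, clin_cols, drop = FALSE]))
    out$clinical_correlations <- clin
    data.table::fwrite(format_num_df(clin),
                       file.path(config$out_dir, "clinical_correlations.tsv"), sep = "\t")
  }
  note("evaluate: top marker %s, AUC %.3f (%.3f-%.3f), sens %.3f, spec %.3f",
       top, roc$auc, roc$ci_low, roc$ci_high, roc$sensitivity, roc$specificity)
  if (!is.null(truth)) {
    out$truth <- truth
    note("truth: top marker %s a planted DMP", if (top %in% truth$planted_probe_ids)
      "IS" else "is NOT")
  }

  writeLines(loglines, logf)
  summary_lines <- c(
    "methmark pipeline summary",
    sprintf("probes retained after QC: %d", fl$report$retained),
    sprintf("selected DMP candidates: %d", nrow(sel)),
    sprintf("CALF final metric: %.4f (empirical p = %.2e)", calf$final_metric, perm$p),
    sprintf("top consensus marker: %s", top),
    sprintf("AUC: %.3f (95%% CI %.3f-%.3f), sensitivity %.3f, specificity %.3f (Youden)",
            roc$auc, roc$ci_low, roc$ci_high, roc$sensitivity, roc$specificity))
  writeLines(summary_lines, file.path(config$out_dir, "summary.txt"))
  invisible(out)
}

## round numeric columns for stable on-disk output
format_num_df <- function(df, digits = 10) {
  for (j in seq_along(df)) if (is.numeric(df[[j]])) df[[j]] <- round(df[[j]], digits)
  df
}
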