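#' Probe-filtering thresholds
#'
#' Defaults follow standard 450K QC practice: a probe is dropped if its
#' detection p-value exceeds 0.01 in one or more samples, if the
#' fraction of samples with bead count below 3 is strictly greater than
#' 5%, or if it lies on a sex chromosome, overlaps a SNP, or is flagged
#' cross-reactive.
#'
#' @param detection_p_max maximum tolerated detection p-value.
#' @param min_bead_count minimum bead count for a reliable measurement.
#' @param max_low_bead_fraction tolerated fraction of low-bead samples
#'   (removal requires strictly greater).
#' @param drop_sex_chromosomes,drop_snp_probes,drop_cross_reactive
#'   logical switches for the annotation-based rules.
#' @return a `filter_thresholds` list.
#' @export
filter_thresholds <- function(detection_p_max = 0.01,
                              min_bead_count = 3L,
                              max_low_bead_fraction = 0.05,
                              drop_sex_chromosomes = TRUE,
                              drop_snp_probes = TRUE,
                              drop_cross_reactive = TRUE) {
  if (detection_p_max <= 0 || detection_p_max >= 1)
    stop_config("detection_p_max", "must be in (0, 1)")
  if (max_low_bead_fraction < 0 || max_low_bead_fraction > 1)
    stop_config("max_low_bead_fraction", "must be in [0, 1]")
  structure(list(detection_p_max = detection_p_max,
                 min_bead_count = min_bead_count,
                 max_low_bead_fraction = max_low_bead_fraction,
                 drop_sex_chromosomes = isTRUE(drop_sex_chromosomes),
                 drop_snp_probes = isTRUE(drop_snp_probes),
                 drop_cross_reactive = isTRUE(drop_cross_reactive)),
            class = "filter_thresholds")
}

#' Quality-control filtering of probes
#'
#' Applies, in order: (a) detection p-value above the threshold in at
#' least one sample; (b) bead count below the minimum in strictly more
#' than the tolerated fraction of samples; (c) sex-chromosome probes;
#' (d) SNP-flagged probes; (e) cross-reactive probes. Each removed
#' probe is attributed to the first rule that fires, so the report's
#' per-rule counts plus the retained count equal the input probe count.
#' The sample set is unchanged; the operation is idempotent.
#'
#' @param dataset a `methyl_dataset`.
#' @param thresholds a [filter_thresholds()].
#' @return list with `dataset` (filtered) and `report` (a
#'   `filter_report` with per-rule removal counts and the rule log).
#' @export
filter_probes <- function(dataset, thresholds = filter_thresholds()) {
  validate_methyl_dataset(dataset)
  np <- nrow(dataset$beta)
  fail_detection <- rowSums(dataset$detection_p > thresholds$detection_p_max) >= 1L
  low_bead_frac <- rowMeans(dataset$bead_count < thresholds$min_bead_count)
  fail_beads <- low_bead_frac > thresholds$max_low_bead_fraction
  fail_sex <- thresholds$drop_sex_chromosomes &
    dataset$annotation$chromosome %in% c("X", "Y")
  fail_snp <- thresholds$drop_snp_probes & dataset$annotation$snp_flag == 1L
  fail_cross <- thresholds$drop_cross_reactive &
    dataset$annotation$cross_reactive_flag == 1L

  rules <- cbind(detection = fail_detection, beads = fail_beads,
                 sex_chr = fail_sex, snp = fail_snp, cross_reactive = fail_cross)
  first_rule <- apply(rules, 1L, function(r) if (any(r)) which(r)[1L] else 0L)
  keep <- first_rule == 0L
  if (!any(keep)) stop("no probes retained after filtering", call. = FALSE)

  removed <- vapply(seq_len(ncol(rules)), function(k) sum(first_rule == k), integer(1))
  names(removed) <- colnames(rules)
  report <- structure(list(
    removed = removed,
    retained = sum(keep),
    input = np,
    rule_order = colnames(rules),
    log = sprintf("rule %-14s removed %6d probe(s)", colnames(rules), removed)
  ), class = "filter_report")

  out <- dataset
  out$beta <- dataset$beta[keep, , drop = FALSE]
  out$detection_p <- dataset$detection_p[keep, , drop = FALSE]
  out$bead_count <- dataset$bead_count[keep, , drop = FALSE]
  out$annotation <- dataset$annotation[keep, , drop = FALSE]
  rownames(out$annotation) <- NULL
  list(dataset = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("probe QC: %d in, %d retained\n", x$input, x$retained))
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}

#' Write a filter report as a machine-readable TSV plus plain-text log
#' @param report a `filter_report`.
#' @param file output TSV path; a `.log` sibling holds the text log.
#' @return invisibly, `file`.
#' @export
write_filter_report <- function(report, file) {
  df <- data.frame(rule = c(report$rule_order, "retained"),
                   probes = c(unname(report$removed), report$retained))
  data.table::fwrite(df, file, sep = "\t")
  writeLines(c(sprintf("probe QC: %d in, %d retained", report$input, report$retained),
               report$log), sub("\\.tsv$", ".log", file))
  invisible(file)
}
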