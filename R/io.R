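## Tab-separated on-disk layout:
##   beta.tsv / detection_p.tsv / bead_count.tsv : probe_id + one column
##     per sample_id
##   annotation.tsv : probe_id, chromosome, design_type, snp_flag,
##     cross_reactive_flag, gene_symbol
##   samples.tsv    : sample_id, group, age, sex, batch_id, iq,
##     ados_total, assq_total
##   truth.json     : optional ground-truth sidecar
## Betas and detection p-values are written with 6 decimals; the round
## trip is lossless at that precision.

#' Write a methylation dataset to a directory of TSV files
#'
#' @param dataset a `methyl_dataset`.
#' @param directory output directory (created if absent).
#' @param truth optional `truth_record` written as `truth.json`.
#' @return invisibly, the vector of files written.
#' @export
write_dataset <- function(dataset, directory, truth = NULL) {
  validate_methyl_dataset(dataset)
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  write_mat <- function(mat, file, digits = 6) {
    df <- data.table::data.table(probe_id = rownames(mat))
    vals <- if (is.integer(mat)) mat else round(mat, digits)
    for (j in seq_len(ncol(mat))) df[[colnames(mat)[j]]] <- vals[, j]
    data.table::fwrite(df, file, sep = "\t")
  }
  files <- file.path(directory, c("beta.tsv", "detection_p.tsv", "bead_count.tsv",
                                  "annotation.tsv", "samples.tsv"))
  write_mat(dataset$beta, files[1])
  write_mat(dataset$detection_p, files[2])
  write_mat(dataset$bead_count, files[3])
  data.table::fwrite(dataset$annotation, files[4], sep = "\t")
  data.table::fwrite(dataset$samples, files[5], sep = "\t")
  if (!is.null(truth)) {
    tf <- file.path(directory, "truth.json")
    jsonlite::write_json(list(
      planted_probe_ids = truth$planted_probe_ids,
      delta_beta = as.list(truth$delta_beta),
      batch_shift = as.list(truth$batch_shift),
      batch_scale = as.list(truth$batch_scale),
      cell_props = as.data.frame(truth$cell_props),
      cell_reference = cbind(data.frame(probe_id = rownames(truth$cell_reference)),
                             as.data.frame(truth$cell_reference)),
      config = truth$config[!vapply(truth$config, is.list, logical(1))]
    ), tf, auto_unbox = TRUE, digits = 10)
    files <- c(files, tf)
  }
  invisible(files)
}

fmt_err <- function(file, msg) {
  stop(sprintf("format error in %s: %s", file, msg), call. = FALSE)
}

read_matrix_tsv <- function(file, integer = FALSE) {
  if (!file.exists(file)) stop(sprintf("missing file: %s", file), call. = FALSE)
  dt <- data.table::fread(file, sep = "\t", header = TRUE, data.table = FALSE)
  if (names(dt)[1] != "probe_id") fmt_err(file, "first column must be 'probe_id'")
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- dt$probe_id
  if (!is.numeric(m)) fmt_err(file, "non-numeric values in matrix body")
  if (integer) storage.mode(m) <- "integer"
  m
}

#' Read a methylation dataset from a directory of TSV files
#'
#' Validates dimensions, headers and value ranges; out-of-range betas
#' are rejected with the offending probe and sample named.
#'
#' @param directory directory containing the files written by
#'   [write_dataset()].
#' @return a `methyl_dataset`.
#' @export
read_dataset <- function(directory) {
  beta <- read_matrix_tsv(file.path(directory, "beta.tsv"))
  bad <- which(beta < 0 | beta > 1, arr.ind = TRUE)
  if (nrow(bad))
    fmt_err(file.path(directory, "beta.tsv"),
            sprintf("beta value %g out of [0,1] at probe '%s', sample '%s'",
                    beta[bad[1, 1], bad[1, 2]],
                    rownames(beta)[bad[1, 1]], colnames(beta)[bad[1, 2]]))
  detection_p <- read_matrix_tsv(file.path(directory, "detection_p.tsv"))
  bead_count <- read_matrix_tsv(file.path(directory, "bead_count.tsv"), integer = TRUE)

  af <- file.path(directory, "annotation.tsv")
  if (!file.exists(af)) stop(sprintf("missing file: %s", af), call. = FALSE)
  annotation <- data.table::fread(af, sep = "\t", header = TRUE, data.table = FALSE,
                                  colClasses = list(character = c("probe_id", "chromosome")))
  req <- c("probe_id", "chromosome", "design_type", "snp_flag", "cross_reactive_flag")
  miss <- setdiff(req, names(annotation))
  if (length(miss)) fmt_err(af, paste("missing column(s):", paste(miss, collapse = ", ")))

  sf <- file.path(directory, "samples.tsv")
  if (!file.exists(sf)) stop(sprintf("missing file: %s", sf), call. = FALSE)
  samples <- data.table::fread(sf, sep = "\t", header = TRUE, data.table = FALSE)
  ## numeric sample covariates are doubles regardless of how they print
  for (j in names(samples))
    if (is.integer(samples[[j]])) samples[[j]] <- as.double(samples[[j]])
  miss <- setdiff(c("sample_id", "group", "age", "sex", "batch_id"), names(samples))
  if (length(miss)) fmt_err(sf, paste("missing column(s):", paste(miss, collapse = ", ")))

  if (!identical(rownames(beta), annotation$probe_id))
    fmt_err(af, "probe_id order disagrees with beta.tsv")
  if (!identical(colnames(beta), samples$sample_id))
    fmt_err(sf, "sample_id order disagrees with beta.tsv header")
  if (!identical(dim(beta), dim(detection_p)) || !identical(dim(beta), dim(bead_count)))
    fmt_err(file.path(directory, "detection_p.tsv"), "matrix dimension mismatch")

  methyl_dataset(beta, detection_p, bead_count, annotation, samples)
}
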