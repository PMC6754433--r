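#' Reference-based leukocyte deconvolution by constrained projection
#'
#' Houseman-style estimation: for each sample, the beta vector over the
#' reference's discriminating probes is projected onto the six
#' cell-type mean profiles by nonnegative least squares
#' (minimize ||y - R w||^2 subject to w >= 0), and the solution is
#' renormalized to sum to one. The residual norm of the unnormalized
#' fit is retained so no fit information is lost. Probes are matched by
#' id; at least half the reference probes must be present.
#'
#' @param dataset a `methyl_dataset`.
#' @param reference numeric matrix, reference probes x 6 cell types
#'   (rownames = probe ids), values in `[0, 1]`.
#' @return a `cell_proportions` object: `proportions` (samples x 6,
#'   rows sum to 1), `residual_norm`, `n_probes_used`, and
#'   `conditioning_warning` if the reference is nearly collinear.
#' @export
estimate_proportions <- function(dataset, reference) {
  validate_methyl_dataset(dataset)
  if (is.null(rownames(reference)) || ncol(reference) != 6L)
    stop("estimate_proportions: reference must have probe rownames and 6 cell-type columns",
         call. = FALSE)
  common <- intersect(rownames(reference), rownames(dataset$beta))
  overlap <- length(common) / nrow(reference)
  if (overlap < 0.5)
    stop(sprintf("estimate_proportions: only %.1f%% of reference probes present (need >= 50%%)",
                 100 * overlap), call. = FALSE)
  r <- as.matrix(reference[common, , drop = FALSE])
  y <- dataset$beta[common, , drop = FALSE]

  cond_warn <- NULL
  kappa_r <- kappa(r, exact = TRUE)
  if (kappa_r > 1e6) {
    cond_warn <- sprintf("reference condition number %.3g; estimates may be unstable", kappa_r)
    warning(cond_warn, call. = FALSE)
  }

  n <- ncol(y)
  props <- matrix(NA_real_, n, ncol(r),
                  dimnames = list(colnames(y), colnames(r)))
  resid_norm <- numeric(n)
  for (s in seq_len(n)) {
    fit <- pracma::lsqnonneg(r, y[, s])
    w <- fit$x
    resid_norm[s] <- sqrt(max(fit$resid.norm, 0))
    if (sum(w) <= 0) w <- rep(1 / length(w), length(w))
    props[s, ] <- w / sum(w)
  }
  structure(list(proportions = props,
                 residual_norm = setNames(resid_norm, colnames(y)),
                 n_probes_used = length(common),
                 conditioning_warning = cond_warn),
            class = "cell_proportions")
}

#' @export
print.cell_proportions <- function(x, ...) {
  cat(sprintf("cell_proportions: %d samples x %d cell types (%d reference probes)\n",
              nrow(x$proportions), ncol(x$proportions), x$n_probes_used))
  print(round(colMeans(x$proportions), 3))
  invisible(x)
}

#' Compare blood cell composition between groups
#'
#' Per cell type, a two-sample Student's t-test (pooled variance) of
#' estimated proportions between the two groups.
#'
#' @param props a `cell_proportions` (or a samples x cell-types matrix).
#' @param samples sample sheet with `sample_id` and `group` columns.
#' @return data.frame: cell_type, mean_case, mean_control, t, df, p.
#' @export
compare_composition <- function(props, samples) {
  p <- if (inherits(props, "cell_proportions")) props$proportions else as.matrix(props)
  grp <- samples$group[match(rownames(p), samples$sample_id)]
  if (anyNA(grp)) stop("compare_composition: sample ids not found in sample sheet",
                       call. = FALSE)
  groups <- unique(grp)
  if (length(groups) != 2L || min(table(grp)) < 2L)
    stop("compare_composition: need two groups with >= 2 samples each", call. = FALSE)
  ca <- if ("case" %in% groups) "case" else groups[1]
  co <- setdiff(groups, ca)[1]
  res <- lapply(colnames(p), function(ct) {
    x <- p[grp == ca, ct]; y <- p[grp == co, ct]
    tt <- two_group_test(x, y)
    data.frame(cell_type = ct, mean_case = mean(x), mean_control = mean(y),
               t = tt$t, df = tt$df, p = tt$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Write / read a cell-type reference matrix as TSV
#' @param reference probes x 6 matrix with probe rownames.
#' @param file TSV path (`probe_id` + six cell-type columns).
#' @return invisibly `file` (write) or the matrix (read).
#' @export
write_cell_reference <- function(reference, file) {
  df <- cbind(data.frame(probe_id = rownames(reference)),
              as.data.frame(round(reference, 6)))
  data.table::fwrite(df, file, sep = "\t")
  invisible(file)
}

#' @rdname write_cell_reference
#' @export
read_cell_reference <- function(file) {
  df <- data.table::fread(file, sep = "\t", header = TRUE, data.table = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$probe_id
  m
}
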