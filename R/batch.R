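#' Empirical-Bayes batch adjustment on the logit scale
#'
#' Betas are mapped to the logit scale and each batch variable is
#' adjusted in sequence (default order: as given) by probe-wise
#' standardization that retains the protected group effect, followed by
#' empirical-Bayes shrinkage of per-batch location and scale parameters
#' toward moment-matched parametric priors (normal location,
#' inverse-gamma scale) — the ComBat model. Adjusted values are mapped
#' back to the beta scale and clipped to `[0, 1]`. A batch variable with
#' a single level is a no-op for that variable.
#'
#' @param dataset a `methyl_dataset`.
#' @param batch_variables character vector of sample-sheet column names
#'   treated as batches, applied sequentially in the given order.
#' @param protect sample-sheet column whose effect is protected
#'   (default `"group"`).
#' @return the adjusted `methyl_dataset`.
#' @export
batch_adjust <- function(dataset, batch_variables = "batch_id", protect = "group") {
  validate_methyl_dataset(dataset)
  samples <- dataset$samples
  miss <- setdiff(c(batch_variables, protect), names(samples))
  if (length(miss))
    stop(sprintf("batch_adjust: sample sheet lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  grp <- factor(samples[[protect]])
  l <- logit(dataset$beta)
  for (bv in batch_variables) {
    batch <- factor(samples[[bv]])
    if (nlevels(batch) < 2L) next
    tab <- table(batch)
    if (any(tab < 2L))
      stop(sprintf("batch_adjust: batch variable '%s' has a level with < 2 samples", bv),
           call. = FALSE)
    ## group must not be determined by batch (perfect confounding)
    xb <- model.matrix(~ 0 + batch)
    xg <- model.matrix(~ 0 + grp)
    if (qr(cbind(xb, xg))$rank < ncol(xb) + ncol(xg) - 1L)
      stop(sprintf("batch_adjust: '%s' is perfectly confounded with '%s'", bv, protect),
           call. = FALSE)
    mod <- model.matrix(~ grp)
    l <- suppressMessages(sva::ComBat(dat = l, batch = batch, mod = mod,
                                      par.prior = TRUE, prior.plots = FALSE))
  }
  out <- dataset
  out$beta <- clip_beta(inv_logit(l))
  dimnames(out$beta) <- dimnames(dataset$beta)
  out
}
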