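## Small shared helpers: logit transforms, seed derivation, argument checks.

BETA_EPS <- 1e-6

clip_beta <- function(x, eps = BETA_EPS) pmin(pmax(x, eps), 1 - eps)

logit <- function(p) qlogis(clip_beta(p))

inv_logit <- function(x) plogis(x)

#' Derive a stage-specific seed from a global seed
#'
#' Stage names are hashed to a 31-bit offset so every pipeline stage gets
#' an independent, reproducible RNG stream from one global seed.
#'
#' @param global_seed integer global seed.
#' @param stage character stage name.
#' @return integer seed below 2^31.
#' @export
derive_seed <- function(global_seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 1998244353
  as.integer((as.numeric(global_seed) %% 65536 * 30011 + h) %% 2147483647)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

check_count <- function(x, field, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop_config(field, sprintf("must be an integer >= %d", min))
  as.integer(x)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_config(field, "must be a probability in [0, 1]")
  as.numeric(x)
}

check_nonneg <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop_config(field, "must be a nonnegative number")
  as.numeric(x)
}

## truncated normal by rejection; bounds may be infinite
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}
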