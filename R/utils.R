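## Internal helpers shared across modules.

#' Derive a deterministic child seed from a master seed and a string key
#'
#' Polynomial rolling hash over the UTF-8 bytes of `key`, folded into the
#' master seed modulo 2^31 - 1. Used to give every (sample, set size)
#' permutation stream, every cohort, and every substituted gene set its
#' own reproducible RNG stream that does not depend on evaluation order.
#'
#' @param seed integer master seed.
#' @param key character scalar stream identifier.
#' @return integer in [0, 2^31 - 2].
#' @keywords internal
derive_seed <- function(seed, key) {
  mod <- 2147483647
  h <- as.double(seed %% mod)
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% mod
  as.integer(h)
}

## Evaluate `expr` under a temporary RNG state seeded by `seed`; the
## caller's RNG state is restored afterwards so seeded subroutines do
## not perturb the surrounding stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## One info line per pipeline stage.
stage_log <- function(...) message("[gsascreen] ", sprintf(...))

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Area under the ROC curve by trapezoidal integration
#'
#' @param scores numeric predicted scores (higher = more likely positive).
#' @param labels 0/1 vector of true classes.
#' @return list with `auc` and a data.frame `roc` of (fpr, tpr) points;
#'   tied scores collapse onto one ROC vertex.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (!all(labels %in% 0:1)) stopf("labels must be 0/1")
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) stopf("both classes required for ROC")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  ## collapse tied score values into single ROC vertices
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last]; fp <- cumsum(1 - y)[last]
  tpr <- c(0, tp / np); fpr <- c(0, fp / nn)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(auc = auc, roc = data.frame(fpr = fpr, tpr = tpr))
}
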