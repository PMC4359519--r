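## Metastasis classification from gene set activity scores: Wilcoxon
## rank-sum feature selection (FDR-controlled) and a random forest
## evaluated by repeated, stratified 10-fold cross-validated AUC. The
## cross-dataset design transfers the feature *list* only; the model is
## always retrained under cross-validation inside the evaluation cohort.

#' Two-sided Wilcoxon rank-sum test, normal approximation
#'
#' Mann-Whitney U with tie-corrected variance and continuity correction;
#' exact enumeration is reserved for test oracles. All observations tied
#' gives p = 1.
#'
#' @param x,y numeric samples.
#' @return list(statistic = U for `x`, p = two-sided p-value).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 > 0L, n2 > 0L)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  N <- n1 + n2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(statistic = U, p = 1))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  list(statistic = U, p = min(1, 2 * pnorm(-abs(z))))
}

#' Select gene set features separating metastatic from non-metastatic samples
#'
#' Per-set two-sided Wilcoxon rank-sum test of GSAS between the two
#' label groups, BH adjustment across the collection, and selection at
#' `q < q_threshold`. Selection consumes only this matrix and its own
#' labels, so cross-cohort transfer can never leak evaluation labels.
#'
#' @param gsas a `gsas_matrix` (sets x samples).
#' @param labels named or column-aligned 0/1 metastasis labels.
#' @param q_threshold BH q cutoff (default 0.01).
#' @param dataset label recorded with the selection.
#' @return `feature_selection` data.frame: set, statistic, p, q,
#'   selected; attribute `selected` holds the chosen names.
#' @export
select_features <- function(gsas, labels, q_threshold = 0.01,
                            dataset = "dataset") {
  if (!is.null(names(labels))) labels <- labels[colnames(gsas)]
  stopifnot(length(labels) == ncol(gsas))
  labels <- as.integer(labels)
  if (length(unique(labels[!is.na(labels)])) < 2L)
    stopf("both metastasis classes must be present")
  ok <- !is.na(labels)
  res <- t(vapply(rownames(gsas), function(s) {
    w <- wilcoxon_rank_sum(gsas[s, ok][labels[ok] == 1L],
                           gsas[s, ok][labels[ok] == 0L])
    c(w$statistic, w$p)
  }, numeric(2)))
  out <- data.frame(set = rownames(gsas), statistic = res[, 1], p = res[, 2],
                    stringsAsFactors = FALSE)
  out$q <- bh_fdr(out$p)
  out$selected <- out$q < q_threshold
  rownames(out) <- NULL
  stage_log("feature selection '%s': %d of %d sets at q < %g", dataset,
            sum(out$selected), nrow(out), q_threshold)
  structure(out, dataset = dataset, q_threshold = q_threshold,
            selected = out$set[out$selected],
            class = c("feature_selection", "data.frame"))
}

## Stratified fold assignment; re-drawn (max 10 tries) if any training
## split would contain a single class.
.stratified_folds <- function(labels, folds, seed) {
  n <- length(labels)
  for (attempt in seq_len(10L)) {
    assign <- with_seed(derive_seed(seed, paste0("folds-", attempt)), {
      f <- integer(n)
      for (cl in unique(labels)) {
        i <- which(labels == cl)
        f[i] <- (sample(seq_along(i)) - 1L) %% folds + 1L
      }
      f
    })
    ok <- all(vapply(seq_len(folds), function(k)
      length(unique(labels[assign != k])) == 2L, TRUE))
    if (ok) return(assign)
    warnf("fold draw %d left a one-class training split; re-drawing", attempt)
  }
  stopf("could not build two-class folds; too few samples per class")
}

#' Cross-validated random forest evaluation of selected features
#'
#' Stratified `folds`-fold assignment, a random forest (default 500
#' trees, sqrt(p) candidate features per split) trained per fold,
#' out-of-fold class probabilities pooled per repeat, AUC by trapezoid,
#' averaged over `repeats`. Feature importance is the Gini impurity
#' decrease averaged over all trees.
#'
#' @param gsas a `gsas_matrix` of the evaluation cohort.
#' @param labels named or aligned 0/1 metastasis labels.
#' @param features a [select_features()] result (possibly from another
#'   cohort) or a character vector of set names; intersected with this
#'   matrix's sets.
#' @param folds,repeats cross-validation design (defaults 10 x 10).
#' @param seed master seed for folds and forests.
#' @param ntree,mtry forest size and candidate features per split
#'   (default 500 and floor(sqrt(p))).
#' @return `cv_evaluation`: list with `auc_per_repeat`, `mean_auc`,
#'   `roc` (pooled across repeats), `importance` (named, averaged),
#'   `features`, `folds`, `repeats`, `seed`.
#' @export
evaluate_cv <- function(gsas, labels, features, folds = 10L, repeats = 10L,
                        seed = 1L, ntree = 500L, mtry = NULL) {
  feat <- if (inherits(features, "feature_selection"))
    attr(features, "selected") else as.character(features)
  feat <- intersect(feat, rownames(gsas))
  if (!length(feat)) stopf("no selected features present in this matrix")
  if (folds < 2L) stopf("folds must be >= 2")
  if (!is.null(names(labels))) labels <- labels[colnames(gsas)]
  stopifnot(length(labels) == ncol(gsas))
  labels <- as.integer(labels)
  ok <- !is.na(labels)
  X <- t(unclass(gsas)[feat, ok, drop = FALSE])
  y <- labels[ok]
  if (length(unique(y)) < 2L) stopf("both classes required")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(length(feat))))
  stage_log("cross-validation: %d features, %d samples, %dx%d-fold, %d trees",
            length(feat), nrow(X), repeats, folds, ntree)

  aucs <- numeric(repeats)
  all_prob <- numeric(0); all_lab <- integer(0)
  imp <- setNames(numeric(length(feat)), feat)
  for (r in seq_len(repeats)) {
    assign <- .stratified_folds(y, folds, derive_seed(seed, paste0("rep-", r)))
    prob <- numeric(nrow(X))
    for (k in seq_len(folds)) {
      te <- assign == k
      if (!any(te)) next
      fit <- with_seed(derive_seed(seed, sprintf("rf-%d-%d", r, k)),
                       .rf_fit_predict_cpp(X[!te, , drop = FALSE], y[!te],
                                           X[te, , drop = FALSE],
                                           as.integer(ntree),
                                           as.integer(mtry)))
      prob[te] <- fit$prob
      imp <- imp + setNames(fit$importance, feat)
    }
    aucs[r] <- roc_auc(prob, y)$auc
    all_prob <- c(all_prob, prob); all_lab <- c(all_lab, y)
  }
  pooled <- roc_auc(all_prob, all_lab)
  structure(list(auc_per_repeat = aucs, mean_auc = mean(aucs),
                 roc = pooled$roc, importance = imp / (repeats * folds),
                 features = feat, folds = folds, repeats = repeats,
                 seed = seed, ntree = ntree, mtry = mtry),
            class = "cv_evaluation")
}

#' @export
print.cv_evaluation <- function(x, ...) {
  cat(sprintf("cv_evaluation: mean AUC %.3f over %d repeats of %d-fold CV (%d features)\n",
              x$mean_auc, x$repeats, x$folds, length(x$features)))
  invisible(x)
}
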