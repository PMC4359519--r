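## The gene set activity score (GSAS) engine.
##
## For one sample, genes are ranked by relative expression (descending).
## Two empirical CDFs are walked along the ranking: the foreground
## (genes of the target set) and the background (all other genes). The
## preliminary score is the signed maximum deviation between them -- a
## signed Kolmogorov-Smirnov style D statistic in [-1, 1], positive when
## set genes concentrate at the top of the ranking. The GSAS divides the
## preliminary score by the mean |preliminary score| of size-matched
## uniformly random gene sets (1000 permutations by default), so a
## random set has expected |GSAS| ~ 1 regardless of its size.

#' Z-score each gene across the samples of a matrix
#'
#' The "relative expression" transform for one-channel data; genes with
#' zero variance are set to 0 with a warning (two-channel log-ratios
#' can skip this entirely).
#'
#' @param expr expression matrix (genes x samples).
#' @return matrix of the same shape.
#' @export
standardize_expression <- function(expr) {
  n <- ncol(expr)
  mu <- rowMeans(expr)
  sdv <- sqrt(rowSums((expr - mu)^2) / (n - 1))
  zero <- sdv == 0
  if (any(zero)) {
    warnf("%d zero-variance gene(s) z-scored to 0", sum(zero))
    sdv[zero] <- 1
  }
  (expr - mu) / sdv
}

#' Rank genes of one sample by relative expression
#'
#' With `standardize = TRUE` (the default, the meaning of "relative
#' expression" for one-channel data) each gene is first z-scored across
#' the samples of the matrix; two-channel log-ratios can be ranked
#' directly with `standardize = FALSE`. Genes are sorted by descending
#' value; ties break by ascending gene id, which is deterministic and
#' platform-independent.
#'
#' @param expr expression matrix (genes x samples).
#' @param sample sample id (column name).
#' @param standardize z-score each gene across samples first?
#' @return object of class `sample_ranking`: list with `genes` (ordered
#'   ids), `values` (ordered ranking values), `sample`, `n_ties` (genes
#'   involved in tied values).
#' @export
rank_genes <- function(expr, sample, standardize = TRUE) {
  validate_expression(expr)
  if (!sample %in% colnames(expr)) stopf("sample not in matrix: %s", sample)
  v <- if (standardize) standardize_expression(expr)[, sample]
       else expr[, sample]
  ids <- rownames(expr)
  o <- order(-v, ids, method = "radix")
  structure(list(genes = ids[o], values = unname(v[o]), sample = sample,
                 standardize = standardize,
                 n_ties = sum(duplicated(v)) + sum(duplicated(v, fromLast = TRUE)) -
                   sum(duplicated(v) & duplicated(v, fromLast = TRUE))),
            class = "sample_ranking")
}

#' @export
print.sample_ranking <- function(x, ...) {
  cat(sprintf("sample_ranking: %s, %d genes (%d tied)\n",
              x$sample, length(x$genes), x$n_ties))
  invisible(x)
}

#' Preliminary activity score of a gene set in a ranked sample
#'
#' Signed maximum deviation between the set CDF F and the complement CDF
#' B along the ranking: `d+ = max_i (F - B)`, `d- = min_i (F - B)`; the
#' value is `d+` when `d+ >= |d-|`, else `d-`. With `weighted = TRUE`
#' both CDFs accumulate |ranking value| mass instead of gene counts (the
#' magnitude-weighted flavor of the scorer; off by default).
#'
#' @param ranking a [rank_genes()] result.
#' @param gene_set character vector of gene ids; intersected with the
#'   ranking before scoring.
#' @param weighted use magnitude-weighted CDFs?
#' @return list with `value` in [-1, 1], `argmax` (rank position of the
#'   extremum), and `m` (set size after intersection).
#' @export
preliminary_score <- function(ranking, gene_set, weighted = FALSE) {
  stopifnot(inherits(ranking, "sample_ranking"))
  G <- length(ranking$genes)
  pos <- sort.int(which(ranking$genes %in% gene_set))
  m <- length(pos)
  if (m == 0L) stopf("gene set has no genes in the ranking")
  if (m == G) stopf("gene set covers the whole ranking; no background left")
  if (weighted) {
    w <- abs(ranking$values)
    if (sum(w) == 0) w <- rep(1, G)
    value <- .ks_stat_weighted_cpp(pos, w, cumsum(w))
    return(list(value = value, argmax = .argmax_position(pos, G, value, w), m = m))
  }
  j <- seq_len(m)
  gap <- (pos - j) / (G - m)
  at <- j / m - gap         # D at each set position
  before <- (j - 1) / m - gap # D just before each set position
  dplus <- max(at, 0)
  dminus <- min(before, 0)
  value <- if (dplus >= -dminus) dplus else dminus
  argmax <- if (value >= 0) {
    if (dplus > 0) pos[which.max(at)] else G
  } else pos[which.min(before)] - 1L
  list(value = value, argmax = as.integer(argmax), m = m)
}

## Locate the extremum position for the weighted statistic by a direct
## O(G) walk (only used for reporting, not scoring).
.argmax_position <- function(pos, G, value, w) {
  member <- logical(G); member[pos] <- TRUE
  wm <- sum(w[member]); wb <- sum(w[!member])
  D <- cumsum(ifelse(member, w / wm, -w / wb))
  as.integer(which.min(abs(D - value))[1])
}

#' Permutation normalization factor for a (sample, set size) pair
#'
#' Mean |preliminary score| over `n_perm` uniformly drawn gene sets of
#' the given size. The RNG stream is derived deterministically from
#' `(seed, sample id, set_size)`, so the factor is shared by all sets of
#' equal size in a sample and does not depend on evaluation order.
#'
#' @param ranking a [rank_genes()] result.
#' @param set_size gene set size (after intersection), `1 <= m < G`.
#' @param n_perm number of permutations (default 1000).
#' @param seed master seed.
#' @param weighted use the magnitude-weighted statistic?
#' @return positive scalar.
#' @export
normalization_factor <- function(ranking, set_size, n_perm = 1000L, seed = 1L,
                                 weighted = FALSE) {
  stopifnot(inherits(ranking, "sample_ranking"))
  G <- length(ranking$genes)
  if (set_size < 1L || set_size >= G) stopf("set_size must satisfy 1 <= m < G")
  if (n_perm < 1L) stopf("n_perm must be >= 1")
  stream <- derive_seed(seed, paste("perm", ranking$sample, set_size, sep = "|"))
  if (weighted) {
    w <- abs(ranking$values)
    if (sum(w) == 0) w <- rep(1, G)
    with_seed(stream, .perm_mean_abs_cpp(G, as.integer(set_size),
                                         as.integer(n_perm), w, cumsum(w)))
  } else {
    with_seed(stream, .perm_mean_abs_cpp(G, as.integer(set_size),
                                         as.integer(n_perm)))
  }
}

#' Score a gene set collection over all samples of a matrix
#'
#' GSAS(set, sample) = preliminary score / normalization factor for the
#' matching (sample, set size). Sets whose intersection with the matrix
#' genes falls below `min_set_size` (or covers every gene) are skipped
#' and enumerated in the result's `skipped` attribute. Normalization
#' factors are cached per (sample, size); because the permutation null
#' depends only on the size and the RNG stream is keyed by
#' `(seed, sample, size)`, caching is exact, not approximate.
#'
#' @param expr expression matrix (genes x samples).
#' @param collection a [gene_set_collection()].
#' @param n_perm permutations per normalization factor (default 1000).
#' @param seed master seed for the permutation streams.
#' @param min_set_size smallest scorable intersection (default 3).
#' @param standardize,weighted passed to [rank_genes()] /
#'   [preliminary_score()].
#' @return `gsas_matrix`: numeric matrix (sets x samples) with
#'   attributes `norm_factors` (per sample, per size), `n_perm`, `seed`,
#'   `skipped` (data.frame set/reason), `min_set_size`.
#' @export
score_collection <- function(expr, collection, n_perm = 1000L, seed = 1L,
                             min_set_size = 3L, standardize = TRUE,
                             weighted = FALSE) {
  validate_expression(expr)
  stopifnot(inherits(collection, "gene_set_collection"))
  genes <- rownames(expr)
  G <- length(genes)
  idx <- lapply(collection, function(s) which(genes %in% s))
  sizes <- lengths(idx)
  skip_small <- sizes < min_set_size
  skip_full <- sizes >= G
  keep <- !(skip_small | skip_full)
  skipped <- data.frame(
    set = names(collection)[!keep],
    reason = ifelse(skip_small[!keep],
                    sprintf("fewer than %d genes in matrix", min_set_size),
                    "covers all matrix genes"),
    stringsAsFactors = FALSE)
  if (nrow(skipped))
    warnf("%d gene set(s) skipped (size filter)", nrow(skipped))
  if (!any(keep)) stopf("no scorable gene sets after size filtering")
  idx <- idx[keep]
  sizes <- sizes[keep]

  samples <- colnames(expr)
  scores <- matrix(NA_real_, length(idx), length(samples),
                   dimnames = list(names(idx), samples))
  norm_factors <- vector("list", length(samples))
  names(norm_factors) <- samples
  stage_log("scoring %d sets x %d samples (n_perm=%d, %s)",
            length(idx), length(samples), n_perm,
            if (weighted) "weighted" else "unweighted")

  Z <- if (standardize) standardize_expression(expr) else expr
  for (s in samples) {
    rk <- rank_genes(Z, s, standardize = FALSE)
    rank_of <- integer(G)
    rank_of[match(rk$genes, genes)] <- seq_len(G)
    if (weighted) {
      w <- abs(rk$values)
      if (sum(w) == 0) w <- rep(1, G)
      S <- cumsum(w)
    }
    fac <- setNames(numeric(0), character(0))
    for (sz in sort(unique(sizes))) {
      fac[as.character(sz)] <- normalization_factor(
        rk, sz, n_perm = n_perm, seed = seed, weighted = weighted)
    }
    norm_factors[[s]] <- fac
    for (k in seq_along(idx)) {
      pos <- sort.int(rank_of[idx[[k]]])
      val <- if (weighted) .ks_stat_weighted_cpp(pos, w, S)
             else .ks_stat_cpp(pos, G)
      scores[k, s] <- val / fac[[as.character(sizes[[k]])]]
    }
  }
  structure(scores, norm_factors = norm_factors, n_perm = as.integer(n_perm),
            seed = as.integer(seed), skipped = skipped,
            min_set_size = as.integer(min_set_size),
            standardize = standardize, weighted = weighted,
            class = c("gsas_matrix", "matrix", "array"))
}

#' @export
print.gsas_matrix <- function(x, ...) {
  cat(sprintf("gsas_matrix: %d sets x %d samples (n_perm=%d, seed=%d, %d skipped)\n",
              nrow(x), ncol(x), attr(x, "n_perm"), attr(x, "seed"),
              nrow(attr(x, "skipped"))))
  invisible(x)
}

#' Write / read a GSAS matrix as a tab-separated table
#'
#' Sets as rows, samples as columns; a JSON sidecar (`<path>.meta.json`)
#' records seed, permutation count, and skipped sets.
#'
#' @param gsas a `gsas_matrix`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gsas <- function(gsas, path) {
  df <- data.frame(set = rownames(gsas), unclass(gsas)[, , drop = FALSE],
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(n_perm = attr(gsas, "n_perm"), seed = attr(gsas, "seed"),
               min_set_size = attr(gsas, "min_set_size"),
               standardize = attr(gsas, "standardize"),
               weighted = attr(gsas, "weighted"),
               skipped = attr(gsas, "skipped"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_gsas
#' @export
read_gsas <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  structure(m,
            n_perm = as.integer(meta$n_perm %||% NA_integer_),
            seed = as.integer(meta$seed %||% NA_integer_),
            min_set_size = as.integer(meta$min_set_size %||% NA_integer_),
            standardize = isTRUE(meta$standardize),
            weighted = isTRUE(meta$weighted),
            skipped = data.frame(),
            class = c("gsas_matrix", "matrix", "array"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
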