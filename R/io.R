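## Readers and writers for the plain-text formats the pipeline touches:
## GMT gene set collections (MSigDB dialect: tab-separated, no quoting,
## description may be empty), genes x samples expression tables, and
## clinical/survival tables.

#' Construct a gene set collection
#'
#' A `gene_set_collection` is a named list of unique character vectors
#' (the member genes) with a parallel `descriptions` attribute. It is the
#' in-memory form of a GMT file and is convertible to a binary
#' genes-by-sets membership matrix via [membership_matrix()].
#'
#' @param sets named list of character vectors; names are set names.
#' @param descriptions optional character vector, recycled empty.
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || anyNA(names(sets)) || any(names(sets) == ""))
    stopf("every gene set needs a name")
  if (anyDuplicated(names(sets)))
    stopf("duplicate gene set name: %s",
          names(sets)[anyDuplicated(names(sets))])
  if (any(lengths(sets) == 0L)) stopf("empty gene sets are not allowed")
  sets <- lapply(sets, function(g) as.character(g))
  if (any(vapply(sets, anyDuplicated, 0L) > 0L))
    stopf("duplicate genes within a set; deduplicate first")
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  descriptions <- as.character(descriptions)
  stopifnot(length(descriptions) == length(sets))
  structure(sets, descriptions = setNames(descriptions, names(sets)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, sizes %d-%d\n",
              length(x), min(lengths(x)), max(lengths(x))))
  invisible(x)
}

#' @export
`[.gene_set_collection` <- function(x, i) {
  gene_set_collection(unclass(x)[i], attr(x, "descriptions")[i])
}

#' Binary genes-by-sets membership matrix view of a collection
#'
#' @param collection a [gene_set_collection()].
#' @param universe optional gene universe for the rows; defaults to the
#'   union of all member genes in first-appearance order.
#' @return integer 0/1 matrix, genes as rows, sets as columns.
#' @export
membership_matrix <- function(collection, universe = NULL) {
  if (is.null(universe)) universe <- unique(unlist(collection, use.names = FALSE))
  m <- matrix(0L, length(universe), length(collection),
              dimnames = list(universe, names(collection)))
  for (s in names(collection)) {
    hit <- intersect(collection[[s]], universe)
    m[hit, s] <- 1L
  }
  m
}

#' Read a GMT gene set file
#'
#' One set per line: name, description, then member genes, all
#' tab-separated. Duplicate genes within a line are dropped with a
#' warning; a line with fewer than three fields or a repeated set name is
#' an error.
#'
#' @param path file path.
#' @return a [gene_set_collection()], file order preserved.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stopf("malformed GMT line %d: expected >= 3 tab-separated fields", i)
    nm <- f[1]
    if (nm %in% names(sets)) stopf("duplicate gene set name: %s", nm)
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warnf("GMT line %d (%s): %d duplicate gene(s) removed",
            i, nm, sum(duplicated(genes)))
      genes <- unique(genes)
    }
    sets[[nm]] <- genes
    desc[nm] <- f[2]
  }
  gene_set_collection(sets, desc)
}

#' Write a gene set collection as GMT
#'
#' @param collection a [gene_set_collection()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  desc <- attr(collection, "descriptions")
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, desc[[nm]], collection[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a genes-by-samples expression table
#'
#' Tab-separated, first row sample ids, first column gene ids. Rows with
#' any non-numeric cell are rejected naming the gene; duplicate gene
#' rows are collapsed by their mean with a warning.
#'
#' @param path file path.
#' @return numeric matrix (genes x samples) with dimnames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stopf("expression file not found: %s", path)
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stopf("expression table has no numeric columns")
  genes <- as.character(tab[[1]])
  vals <- tab[, -1, drop = FALSE]
  num <- vapply(vals, function(col) {
    suppressWarnings(as.numeric(as.character(col)))
  }, numeric(nrow(tab)))
  if (nrow(tab) == 1L) num <- matrix(num, nrow = 1L)
  bad <- which(apply(num, 1L, anyNA))
  if (length(bad))
    stopf("non-numeric expression value(s) in gene row(s): %s",
          paste(genes[bad], collapse = ", "))
  colnames(num) <- colnames(vals)
  rownames(num) <- genes
  if (anyDuplicated(genes)) {
    dups <- unique(genes[duplicated(genes)])
    warnf("%d duplicate gene id(s) collapsed by mean: %s",
          length(dups), paste(head(dups, 5), collapse = ", "))
    num <- rowsum(num, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
    rownames(num) <- unique(genes)
  }
  validate_expression(num)
}

validate_expression <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stopf("expression matrix needs gene row names and sample column names")
  if (anyDuplicated(rownames(mat))) stopf("duplicate gene ids")
  if (anyDuplicated(colnames(mat))) stopf("duplicate sample ids")
  if (!all(is.finite(mat))) stopf("non-finite expression values")
  mat
}

#' Write a genes-by-samples expression table
#'
#' @param mat numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_expression <- function(mat, path) {
  validate_expression(mat)
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.clinical_optional <- c("age", "tumor_size", "grade", "er_status",
                        "ln_status", "metastasis")

#' Read a clinical/survival table
#'
#' Tab-separated with header. Required columns: `sample`, `time`
#' (non-negative survival months), `event` (1 observed, 0 censored).
#' Recognized optional columns: `age`, `tumor_size`, `grade` (1/2/3),
#' `er_status`, `ln_status`, `metastasis` (all binary except the first
#' three). Grades outside {1,2,3} become missing with a warning.
#'
#' @param path file path.
#' @return data.frame of class `clinical_table`, one row per sample.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stopf("clinical file not found: %s", path)
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (col in c("sample", "time", "event"))
    if (!col %in% names(tab)) stopf("clinical table missing required column: %s", col)
  tab$sample <- as.character(tab$sample)
  tab$time <- as.numeric(tab$time)
  tab$event <- as.numeric(tab$event)
  for (col in intersect(.clinical_optional, names(tab)))
    tab[[col]] <- as.numeric(tab[[col]])
  validate_clinical(tab)
}

validate_clinical <- function(tab) {
  if (anyDuplicated(tab$sample)) stopf("duplicate sample ids in clinical table")
  if (anyNA(tab$time) || any(tab$time < 0)) stopf("survival time must be >= 0")
  if (!all(tab$event %in% c(0, 1))) stopf("event must be 0 or 1")
  if ("grade" %in% names(tab)) {
    bad <- !is.na(tab$grade) & !(tab$grade %in% c(1, 2, 3))
    if (any(bad)) {
      warnf("%d grade value(s) outside {1,2,3} set to missing", sum(bad))
      tab$grade[bad] <- NA_real_
    }
  }
  for (col in intersect(c("er_status", "ln_status", "metastasis"), names(tab))) {
    bad <- !is.na(tab[[col]]) & !(tab[[col]] %in% c(0, 1))
    if (any(bad)) {
      warnf("%d %s value(s) not 0/1 set to missing", sum(bad), col)
      tab[[col]][bad] <- NA_real_
    }
  }
  class(tab) <- c("clinical_table", "data.frame")
  tab
}

#' Write a clinical table
#'
#' @param tab a `clinical_table` (or compatible data.frame).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_clinical <- function(tab, path) {
  write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Align expression and clinical tables on shared samples
#'
#' Reports (never silently drops) the sample overlap, then returns both
#' objects restricted to the shared samples in expression column order.
#'
#' @param expr expression matrix.
#' @param clinical clinical table.
#' @return list(expr, clinical) over the shared samples.
#' @export
align_samples <- function(expr, clinical) {
  shared <- intersect(colnames(expr), clinical$sample)
  stage_log("sample alignment: %d expression, %d clinical, %d shared",
            ncol(expr), nrow(clinical), length(shared))
  if (!length(shared)) stopf("no shared samples between expression and clinical")
  expr <- expr[, shared, drop = FALSE]
  clinical <- clinical[match(shared, clinical$sample), , drop = FALSE]
  rownames(clinical) <- NULL
  list(expr = expr, clinical = clinical)
}
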