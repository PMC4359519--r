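## Gene set overlap networks over survival-significant sets: nodes are
## sets passing the FDR filter in one reference screen, split by hazard
## ratio direction (hr >= 1 "negative"/deleterious vs hr < 1
## "positive"/protective); edges are Jaccard overlaps at or above a
## threshold. The module richest in robust sets yields the core gene
## set by a membership-frequency rule.

#' Jaccard overlap score between two gene sets
#'
#' @param set_a,set_b non-empty character vectors.
#' @return |A n B| / |A u B| in [0, 1].
#' @export
overlap_score <- function(set_a, set_b) {
  if (!length(set_a) || !length(set_b)) stopf("gene sets must be non-empty")
  length(intersect(set_a, set_b)) / length(union(set_a, set_b))
}

## All-pairs Jaccard over a list of sets via the binary membership
## matrix: intersections from crossprod, unions from size sums.
.jaccard_matrix <- function(sets) {
  m <- membership_matrix(gene_set_collection(sets))
  inter <- crossprod(m)
  sz <- diag(inter)
  uni <- outer(sz, sz, "+") - inter
  j <- inter / uni
  diag(j) <- 1
  j
}

#' Build hazard-direction overlap networks over significant sets
#'
#' Nodes are the sets with `fdr_q < q_threshold` in the reference
#' screen, split into a "negative" (hr >= 1, deleterious) and a
#' "positive" (hr < 1, protective) network. Within each direction all
#' pairs are Jaccard-scored and edges with overlap below `min_overlap`
#' are dropped. Overlap uses the sets as stored in the collection (the
#' network stage is expression-independent). Node attributes carry p, q,
#' hazard ratio, set size, a robust flag, and a display size
#' `-log10(p)` (larger node = smaller p).
#'
#' @param screen a [screen_survival()] result for the reference cohort.
#' @param collection the scored [gene_set_collection()].
#' @param q_threshold FDR node filter (default 0.01).
#' @param min_overlap minimum Jaccard overlap kept as an edge
#'   (default 0.20; comparison is `>=`).
#' @param robust_names set names flagged as robust across cohorts.
#' @return list of two `igraph` objects, `negative` (hr >= 1) and
#'   `positive` (hr < 1), each with an `overlap` edge attribute.
#' @export
build_network <- function(screen, collection, q_threshold = 0.01,
                          min_overlap = 0.20, robust_names = character(0)) {
  stopifnot(inherits(screen, "data.frame"))
  shared <- intersect(screen$set, names(collection))
  if (!length(shared)) stopf("screen and collection share no set names")
  scr <- screen[match(shared, screen$set), , drop = FALSE]
  sig <- scr[scr$fdr_q < q_threshold, , drop = FALSE]
  if (!nrow(sig)) warnf("no significant sets at q < %g; networks are empty",
                        q_threshold)
  one <- function(rows, direction) {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    if (nrow(rows)) {
      g <- igraph::add_vertices(
        g, nrow(rows), name = rows$set, p = rows$wald_p, q = rows$fdr_q,
        hazard_ratio = rows$hazard_ratio,
        robust = rows$set %in% robust_names,
        size = lengths(unclass(collection)[rows$set]),
        node_size = -log10(pmax(rows$wald_p, 1e-300)))
      if (nrow(rows) >= 2L) {
        J <- .jaccard_matrix(unclass(collection)[rows$set])
        keep <- which(upper.tri(J) & J >= min_overlap, arr.ind = TRUE)
        if (nrow(keep)) {
          g <- igraph::add_edges(g, rbind(keep[, 1], keep[, 2]),
                                 overlap = J[keep])
        }
      }
    }
    g <- igraph::set_graph_attr(g, "direction", direction)
    g
  }
  neg <- one(sig[sig$hazard_ratio >= 1, , drop = FALSE], "negative")
  pos <- one(sig[sig$hazard_ratio < 1, , drop = FALSE], "positive")
  stage_log("overlap networks: negative %d nodes/%d edges, positive %d/%d",
            igraph::vcount(neg), igraph::ecount(neg),
            igraph::vcount(pos), igraph::ecount(pos))
  list(negative = neg, positive = pos)
}

#' Select the network module richest in robust sets
#'
#' Operationalizes visual module picking as connected components: the
#' component with the most robust-flagged nodes wins; ties go to the
#' larger component, then to the lexicographically smallest member name.
#' With no robust node anywhere, the largest component is returned with
#' a warning. `method = "modularity"` swaps components for greedy
#' modularity communities.
#'
#' @param network one `igraph` network from [build_network()].
#' @param method "components" (default) or "modularity".
#' @return character vector of module set names.
#' @export
select_core_module <- function(network, method = c("components", "modularity")) {
  method <- match.arg(method)
  if (igraph::vcount(network) == 0L) stopf("network is empty")
  membership <- if (method == "components")
    igraph::components(network)$membership
  else igraph::membership(igraph::cluster_fast_greedy(network))
  nm <- igraph::V(network)$name
  robust <- igraph::V(network)$robust
  comps <- split(seq_along(nm), membership)
  n_rob <- vapply(comps, function(i) sum(robust[i]), 0L)
  if (all(n_rob == 0L)) {
    warnf("no component contains a robust set; returning the largest")
    pick_from <- comps
  } else {
    pick_from <- comps[n_rob == max(n_rob)]
  }
  sizes <- lengths(pick_from)
  pick_from <- pick_from[sizes == max(sizes)]
  first <- vapply(pick_from, function(i) min(nm[i]), "")
  sort(nm[pick_from[[order(first)[1]]]])
}

#' Extract the core gene set of a module by membership frequency
#'
#' A gene belongs to the core when it appears in at least
#' `freq_threshold` (default 40%) of the module's sets; the comparison
#' is inclusive.
#'
#' @param module character vector of module set names.
#' @param collection the [gene_set_collection()].
#' @param freq_threshold inclusive frequency cutoff in (0, 1].
#' @return `core_gene_set`: list with `genes`, `frequency` (named, for
#'   the core genes), `module`, `threshold`.
#' @export
derive_core_set <- function(module, collection, freq_threshold = 0.40) {
  module <- as.character(module)
  if (!length(module)) stopf("module is empty")
  missing <- setdiff(module, names(collection))
  if (length(missing)) stopf("module sets not in collection: %s",
                             paste(missing, collapse = ", "))
  freq <- gene_frequency(module, collection, min_fraction = 0)
  core <- freq$gene[freq$frequency >= freq_threshold]
  if (!length(core)) warnf("no gene reaches frequency %g; core is empty",
                           freq_threshold)
  structure(list(genes = core,
                 frequency = setNames(freq$frequency, freq$gene)[core],
                 module = module, threshold = freq_threshold),
            class = "core_gene_set")
}

#' @export
print.core_gene_set <- function(x, ...) {
  cat(sprintf("core_gene_set: %d genes from a %d-set module (threshold %g)\n",
              length(x$genes), length(x$module), x$threshold))
  invisible(x)
}

#' Gene membership frequencies over a group of sets
#'
#' @param group character vector of set names.
#' @param collection the [gene_set_collection()].
#' @param min_fraction keep genes present in at least this fraction of
#'   the group's sets (0 = union of all genes).
#' @return data.frame (gene, count, frequency), frequency descending.
#' @export
gene_frequency <- function(group, collection, min_fraction = 0.05) {
  group <- as.character(group)
  if (!length(group)) stopf("group is empty")
  sets <- unclass(collection)[group]
  counts <- table(unlist(lapply(sets, unique), use.names = FALSE))
  out <- data.frame(gene = names(counts), count = as.integer(counts),
                    frequency = as.numeric(counts) / length(group),
                    stringsAsFactors = FALSE)
  out <- out[out$frequency >= min_fraction, , drop = FALSE]
  out <- out[order(-out$frequency, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export an overlap network as GraphML and SIF
#'
#' @param network an `igraph` network from [build_network()].
#' @param graphml,sif output paths (either may be NULL to skip).
#' @return invisibly, the paths written.
#' @export
export_network <- function(network, graphml = NULL, sif = NULL) {
  written <- character(0)
  if (!is.null(graphml)) {
    igraph::write_graph(network, graphml, format = "graphml")
    written <- c(written, graphml)
  }
  if (!is.null(sif)) {
    el <- igraph::as_edgelist(network)
    lines <- if (nrow(el)) sprintf("%s\toverlap\t%s", el[, 1], el[, 2])
             else character(0)
    iso <- setdiff(igraph::V(network)$name, as.vector(el))
    writeLines(c(lines, iso), sif)
    written <- c(written, sif)
  }
  invisible(written)
}
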