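mk_screen <- function(sets, hr, p, label = "ref") {
  structure(data.frame(set = sets, coef = log(hr), hazard_ratio = hr,
                       wald_p = p, fdr_q = bh_fdr(p), n = 100, events = 60,
                       converged = TRUE, stringsAsFactors = FALSE),
            dataset = label, class = c("survival_screen", "data.frame"))
}

test_that("overlap_score is the Jaccard index", {
  expect_equal(overlap_score(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(overlap_score(c("a", "b"), c("a", "b")), 1.0)
  expect_equal(overlap_score(c("a"), c("b")), 0)
  expect_error(overlap_score(character(0), "a"), "non-empty")
  set.seed(17)
  pool <- sprintf("g%03d", 1:60)
  for (i in 1:100) {
    a <- sample(pool, sample(3:30, 1)); b <- sample(pool, sample(3:30, 1))
    expect_identical(overlap_score(a, b), jaccard_oracle(a, b))
  }
})

test_that("build_network splits by hazard direction and thresholds edges", {
  coll <- gene_set_collection(list(
    DEL1 = sprintf("g%02d", 1:10), DEL2 = sprintf("g%02d", 3:12),
    PROT = sprintf("g%02d", 1:10), NS = sprintf("g%02d", 40:49)))
  scr <- mk_screen(names(coll), hr = c(1.3, 1.1, 0.8, 1.5),
                   p = c(1e-5, 1e-4, 1e-4, 0.4))
  nets <- quiet(build_network(scr, coll, q_threshold = 0.01,
                              robust_names = "DEL1"))
  expect_setequal(igraph::V(nets$negative)$name, c("DEL1", "DEL2"))
  expect_setequal(igraph::V(nets$positive)$name, "PROT")
  ## DEL1/DEL2 share 8 of 12 genes -> 0.667 >= 0.2: one edge
  expect_equal(igraph::ecount(nets$negative), 1)
  expect_equal(igraph::E(nets$negative)$overlap, 8 / 12, tolerance = 1e-12)
  ## DEL1 and PROT are identical sets but in different directions: no edge
  expect_equal(igraph::ecount(nets$positive), 0)
  expect_true(igraph::V(nets$negative)$robust[
    igraph::V(nets$negative)$name == "DEL1"])

  strict <- quiet(build_network(scr, coll, q_threshold = 0.01,
                                min_overlap = 1.0))
  expect_equal(igraph::ecount(strict$negative), 0) # only identical sets pass
})

test_that("edge count is monotone non-increasing in the overlap threshold", {
  fx <- bench_fixture()
  counts <- vapply(c(0.05, 0.2, 0.5, 0.9), function(th) {
    nets <- quiet(build_network(fx$screens[[1]], fx$bench$collection,
                                q_threshold = 0.01, min_overlap = th))
    igraph::ecount(nets$negative) + igraph::ecount(nets$positive)
  }, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("benchmark network edges equal all-pairs oracle filtering", {
  fx <- bench_fixture()
  nets <- quiet(build_network(fx$screens[[1]], fx$bench$collection,
                              q_threshold = 0.01))
  net <- nets$negative
  nm <- igraph::V(net)$name
  expect_gte(length(nm), 2)
  el <- igraph::as_edgelist(net)
  got <- sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  want <- character(0)
  sets <- unclass(fx$bench$collection)
  for (i in seq_along(nm)) for (j in seq_len(i - 1)) {
    if (jaccard_oracle(sets[[nm[i]]], sets[[nm[j]]]) >= 0.20)
      want <- c(want, paste(min(nm[i], nm[j]), max(nm[i], nm[j])))
  }
  expect_setequal(got, sort(want))
})

test_that("select_core_module follows the robust-count rule", {
  coll <- gene_set_collection(list(
    A1 = sprintf("a%02d", 1:10), A2 = sprintf("a%02d", 1:10),
    A3 = sprintf("a%02d", 2:11), B1 = sprintf("b%02d", 1:10),
    B2 = sprintf("b%02d", 1:10)))
  scr <- mk_screen(names(coll), hr = rep(1.2, 5), p = rep(1e-5, 5))
  nets <- quiet(build_network(scr, coll, q_threshold = 0.05,
                              robust_names = c("A1", "A2", "A3")))
  expect_setequal(select_core_module(nets$negative), c("A1", "A2", "A3"))
  ## no robust nodes anywhere: largest component with a warning
  nets2 <- quiet(build_network(scr, coll, q_threshold = 0.05))
  expect_warning(mod <- select_core_module(nets2$negative), "robust")
  expect_setequal(mod, c("A1", "A2", "A3"))
  ## singleton network
  scr1 <- mk_screen("A1", 1.2, 1e-5)
  net1 <- quiet(build_network(scr1, coll[1], q_threshold = 0.05,
                              robust_names = "A1"))
  expect_identical(select_core_module(net1$negative), "A1")
})

test_that("derive_core_set applies the inclusive 40% boundary exactly", {
  sets <- list(M1 = c("g1", "g2"), M2 = c("g1", "g3"), M3 = c("g1", "g4"),
               M4 = c("g2", "g5"), M5 = c("g6", "g7"))
  coll <- gene_set_collection(sets)
  core <- derive_core_set(names(sets), coll, freq_threshold = 0.40)
  expect_true("g1" %in% core$genes)  # 3/5 = 60%
  expect_true("g2" %in% core$genes)  # 2/5 = 40%, inclusive boundary
  expect_false("g3" %in% core$genes) # 1/5 = 20%
  ## threshold limits: -> 0 gives the union, 1.0 the intersection
  expect_setequal(derive_core_set(names(sets), coll, 1e-9)$genes,
                  unique(unlist(sets)))
  expect_length(suppressWarnings(
    derive_core_set(names(sets), coll, 1.0))$genes, 0)
  common <- derive_core_set(c("M1", "M2", "M3"), coll, 1.0)
  expect_identical(common$genes, "g1")
})

test_that("gene_frequency matches a counting oracle", {
  set.seed(23)
  sets <- lapply(1:10, function(i) sample(sprintf("g%02d", 1:30), 8))
  names(sets) <- sprintf("S%02d", 1:10)
  coll <- gene_set_collection(sets)
  gf <- gene_frequency(names(sets), coll, min_fraction = 0.3)
  cnt <- table(unlist(sets))
  for (k in seq_len(nrow(gf)))
    expect_equal(gf$count[k], unname(cnt[gf$gene[k]]))
  expect_true(all(gf$frequency >= 0.3))
  expect_setequal(gene_frequency(names(sets), coll, 0)$gene,
                  unique(unlist(sets)))
  expect_equal(nrow(gene_frequency(names(sets), coll,
                                   max(gf$frequency) + 1e-9)), 0)
})

test_that("networks export to GraphML and SIF", {
  coll <- gene_set_collection(list(A = letters[1:5], B = letters[2:6],
                                   C = letters[20:24]))
  scr <- mk_screen(names(coll), hr = c(1.2, 1.3, 1.1), p = rep(1e-4, 3))
  nets <- quiet(build_network(scr, coll, q_threshold = 0.05))
  gml <- withr::local_tempfile(fileext = ".graphml")
  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(nets$negative, graphml = gml, sif = sif)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_setequal(igraph::V(back)$name, c("A", "B", "C"))
  expect_equal(igraph::ecount(back), 1) # only A-B overlap 4/6
  lines <- readLines(sif)
  expect_true(any(grepl("A\toverlap\tB", lines)))
  expect_true("C" %in% lines) # isolated node listed alone
})
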