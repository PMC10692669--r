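write_prior_tsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

# annotated network from explicit node/edge tables
make_annotated <- function(nodes, edges) {
  g <- igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
  attr(g, "treatment") <- "trt"
  attr(g, "parent_hash") <- "h"
  class(g) <- c("annotated_network", class(g))
  g
}

test_that("prior loading drops self-loops, merges duplicates, validates input", {
  p <- write_prior_tsv(data.frame(
    ENTITYA = c("A", "B", "C", "A", "A"), ENTITYB = c("B", "C", "C", "B", "B"),
    EFFECT = c("up-regulates", "down-regulates", "up-regulates", "up-regulates", "up-regulates"),
    MECHANISM = "phosphorylation",
    RESIDUE = c("S5", "T2", "S1", "T7", "S5")))
  expect_message(net <- load_prior(p), "1 self-loop")
  expect_equal(igraph::vcount(net), 3)
  expect_equal(igraph::ecount(net), 2)
  ed <- igraph::as_data_frame(net, what = "edges")
  expect_setequal(strsplit(ed$residues[ed$from == "A"], ",")[[1]], c("S5", "T7"))
  expect_equal(ed$sign[ed$from == "B"], -1L)
  # missing column named in the error
  bad <- tempfile(); writeLines("ENTITYA\tENTITYB\nA\tB", bad)
  expect_error(load_prior(bad), "EFFECT")
  # empty edge table
  empty <- write_prior_tsv(data.frame(ENTITYA = character(), ENTITYB = character(),
                                      EFFECT = character(), MECHANISM = character(),
                                      RESIDUE = character()))
  expect_error(load_prior(empty), "zero edges")
  # round trip through the writer
  p2 <- tempfile(fileext = ".tsv")
  write_signor(net, p2)
  net2 <- load_prior(p2)
  expect_identical(igraph::as_data_frame(net, what = "edges"),
                   igraph::as_data_frame(net2, what = "edges"))
})

test_that("annotation maps activities to nodes and best sites to edges", {
  net <- gen_prior_network(4, 4, 0.4, seed = 13)
  enr <- data.frame(signature = c("KIN01", "KIN02"), category = "KINASE",
                    es = c(1, -1), nes = c(2.5, -3), p = c(0.01, 0.001),
                    fdr = c(0.02, 0.004), overlap = 3L, note = "")
  ed <- igraph::as_data_frame(net, what = "edges")
  res1 <- strsplit(ed$residues[1], ",")[[1]][1]
  diff <- data.frame(protein = ed$to[1], residue = sub("[0-9]+$", "", res1),
                     position = as.integer(sub("^[A-Z]", "", res1)),
                     multiplicity = 1L, treatment = "trt",
                     log2fc = -2.2, p = 1e-4, fdr = 1e-3, mean_control = 1)
  a <- annotate_network(net, enr, diff)
  expect_equal(igraph::V(a)$nes[igraph::V(a)$name == "KIN01"], 2.5)
  expect_true(is.na(igraph::V(a)$nes[igraph::V(a)$name == "KIN03"]))
  expect_equal(igraph::E(a)$log2fc[1], -2.2)
  expect_equal(igraph::E(a)$edge_fdr[1], 1e-3)
  expect_true(all(is.na(igraph::E(a)$log2fc[-1])))
})

test_that("toy extraction: path connectors join perturbed nodes two hops apart", {
  nodes <- data.frame(name = c("A", "B", "C"), nes = c(3, NA, -2),
                      node_fdr = c(0.01, NA, 0.02))
  edges <- data.frame(from = c("A", "B"), to = c("B", "C"), sign = 1L,
                      mechanism = "p", residues = "S1",
                      log2fc = NA_real_, edge_fdr = NA_real_, site = NA_character_)
  s <- extract_subnetwork(make_annotated(nodes, edges))
  expect_setequal(igraph::V(s$graph)$name, c("A", "B", "C"))
  prov <- stats::setNames(igraph::V(s$graph)$provenance, igraph::V(s$graph)$name)
  expect_equal(unname(prov["B"]), "path_connector")
  expect_equal(unname(prov["A"]), "perturbed_node")
  expect_equal(unique(igraph::E(s$graph)$provenance), "path_connector")
  # matches the brute-force oracle
  orc <- oracle_extract(nodes, cbind(edges, stringsAsFactors = FALSE))
  expect_equal(subnetwork_as_sets(s)$nodes, orc$nodes)
  expect_equal(subnetwork_as_sets(s)$edges, orc$edges)
})

test_that("nodes three hops apart stay unconnected; larger fragment wins", {
  nodes <- data.frame(name = c("A", "B", "C", "D"),
                      nes = c(3, NA, NA, 2), node_fdr = c(0.01, NA, NA, 0.02))
  edges <- data.frame(from = c("A", "B", "C", "D"), to = c("B", "C", "D", "E"),
                      sign = 1L, mechanism = "p", residues = "S1",
                      log2fc = c(-2, NA, NA, NA), edge_fdr = c(0.001, NA, NA, NA),
                      site = NA_character_)
  nodes <- rbind(nodes, data.frame(name = "E", nes = NA, node_fdr = NA))
  s <- extract_subnetwork(make_annotated(nodes, edges))
  # A-D distance 3: no path added; A-B perturbed edge forms the larger fragment
  expect_setequal(igraph::V(s$graph)$name, c("A", "B"))
  orc <- oracle_extract(nodes, edges)
  expect_equal(subnetwork_as_sets(s)$nodes, orc$nodes)
})

test_that("a single perturbed edge with no perturbed nodes forms the subnetwork", {
  nodes <- data.frame(name = c("A", "B", "C"), nes = NA_real_, node_fdr = NA_real_)
  edges <- data.frame(from = c("A", "B"), to = c("B", "C"), sign = 1L,
                      mechanism = "p", residues = "S1",
                      log2fc = c(1.5, NA), edge_fdr = c(0.01, NA), site = NA)
  s <- extract_subnetwork(make_annotated(nodes, edges))
  expect_setequal(igraph::V(s$graph)$name, c("A", "B"))
  expect_equal(igraph::E(s$graph)$provenance, "perturbed_edge")
})

test_that("no annotation at all warns and returns an empty subnetwork", {
  nodes <- data.frame(name = c("A", "B"), nes = NA_real_, node_fdr = NA_real_)
  edges <- data.frame(from = "A", to = "B", sign = 1L, mechanism = "p",
                      residues = "S1", log2fc = NA_real_, edge_fdr = NA_real_,
                      site = NA)
  expect_warning(s <- extract_subnetwork(make_annotated(nodes, edges)), "empty")
  expect_equal(igraph::vcount(s$graph), 0)
})

test_that("extraction equals the exhaustive oracle on random annotated graphs", {
  for (seed in 1:60) {
    ra <- random_annotated_graph(seed)
    s <- suppressWarnings(extract_subnetwork(ra$graph))
    orc <- oracle_extract(ra$nodes, ra$edges)
    got <- subnetwork_as_sets(s)
    expect_equal(got$nodes, orc$nodes, info = paste("seed", seed))
    expect_equal(got$edges, orc$edges, info = paste("seed", seed))
  }
})

test_that("relaxing FDR gates never shrinks the perturbed element sets", {
  ra <- random_annotated_graph(123)
  tight <- suppressWarnings(extract_subnetwork(ra$graph, 0.02, 0.02))
  # perturbed sets are monotone in the thresholds by construction of the gates
  nf <- ra$nodes$node_fdr
  ef <- ra$edges$edge_fdr
  for (thr in c(0.02, 0.05, 0.2, 0.5)) {
    pn <- ra$nodes$name[!is.na(nf) & nf <= thr]
    pe <- which(!is.na(ef) & ef <= thr)
    if (thr > 0.02) {
      expect_true(all(ra$nodes$name[!is.na(nf) & nf <= 0.02] %in% pn))
      expect_true(all(which(!is.na(ef) & ef <= 0.02) %in% pe))
    }
  }
  expect_true(igraph::vcount(tight$graph) >= 0)
})

test_that("pruning removes an unannotated redundant path in a diamond", {
  # A -> B -> C fully phosphosite-annotated; A -> X -> C unannotated
  nodes <- data.frame(name = c("A", "B", "C", "X"),
                      nes = c(2, NA, 2, NA), node_fdr = c(0.01, NA, 0.01, NA))
  edges <- data.frame(from = c("A", "B", "A", "X"), to = c("B", "C", "X", "C"),
                      sign = 1L, mechanism = "p", residues = "S1",
                      log2fc = c(1.2, -1.1, NA, NA),
                      edge_fdr = c(0.5, 0.5, NA, NA), site = NA)
  s <- extract_subnetwork(make_annotated(nodes, edges))
  expect_setequal(igraph::V(s$graph)$name, c("A", "B", "C", "X"))
  p <- prune_redundant_paths(s)
  expect_setequal(igraph::V(p$graph)$name, c("A", "B", "C"))
  ped <- igraph::as_data_frame(p$graph, what = "edges")
  expect_setequal(paste(ped$from, ped$to), c("A B", "B C"))
  # connectivity preserved
  expect_equal(igraph::components(igraph::as_undirected(p$graph))$no, 1)
})

test_that("pruning keeps everything when no alternative is fully annotated", {
  nodes <- data.frame(name = c("A", "B", "C", "X"),
                      nes = c(2, NA, 2, NA), node_fdr = c(0.01, NA, 0.01, NA))
  edges <- data.frame(from = c("A", "B", "A", "X"), to = c("B", "C", "X", "C"),
                      sign = 1L, mechanism = "p", residues = "S1",
                      log2fc = c(1.2, NA, NA, NA), edge_fdr = c(0.5, NA, NA, NA),
                      site = NA)
  s <- extract_subnetwork(make_annotated(nodes, edges))
  p <- prune_redundant_paths(s)
  expect_setequal(igraph::V(p$graph)$name, igraph::V(s$graph)$name)
  expect_equal(igraph::ecount(p$graph), igraph::ecount(s$graph))
})

test_that("pruning spares connectors that serve another retained path", {
  # pairs (A,C) via B (annotated) and via X (unannotated), but X also carries
  # the only shortest path for pair (D, C): X must survive
  nodes <- data.frame(name = c("A", "B", "C", "X", "D"),
                      nes = c(2, NA, 2, NA, 2),
                      node_fdr = c(0.01, NA, 0.01, NA, 0.01))
  edges <- data.frame(from = c("A", "B", "A", "X", "D"),
                      to = c("B", "C", "X", "C", "X"),
                      sign = 1L, mechanism = "p", residues = "S1",
                      log2fc = c(1, 1, NA, NA, NA),
                      edge_fdr = c(0.5, 0.5, NA, NA, NA), site = NA)
  s <- extract_subnetwork(make_annotated(nodes, edges))
  p <- prune_redundant_paths(s)
  expect_true("X" %in% igraph::V(p$graph)$name)
  ped <- igraph::as_data_frame(p$graph, what = "edges")
  expect_true("X C" %in% paste(ped$from, ped$to))  # needed by D -> X -> C
  # pruning never removes perturbed nodes
  expect_true(all(c("A", "C", "D") %in% igraph::V(p$graph)$name))
})

test_that("merging counts shared nodes and refuses mixed parents", {
  ra <- random_annotated_graph(77, n_nodes = 12)
  s1 <- suppressWarnings(extract_subnetwork(ra$graph))
  s1$treatment <- "t1"
  s2 <- s1; s2$treatment <- "t2"
  m <- merge_subnetworks(list(s1, s2, s1))
  expect_equal(unique(igraph::V(m$graph)$n_subgraphs), 3L)
  expect_equal(sort(igraph::V(m$graph)$name), sort(igraph::V(s1$graph)$name))
  # disjoint union
  rb <- random_annotated_graph(78, n_nodes = 12)
  s3 <- suppressWarnings(extract_subnetwork(rb$graph))
  s3$parent_hash <- s1$parent_hash
  s3$treatment <- "t3"
  if (length(intersect(igraph::V(s3$graph)$name, igraph::V(s1$graph)$name)) == 0) {
    mu <- merge_subnetworks(list(s1, s3))
    expect_true(all(igraph::V(mu$graph)$n_subgraphs == 1L))
  }
  s4 <- s3; s4$parent_hash <- "other"
  expect_error(merge_subnetworks(list(s1, s4)), "different parent")
})

test_that("centralities: star, triangle, singleton and dense-eigen oracle", {
  star <- igraph::graph_from_edgelist(
    cbind("HUB", c("L1", "L2", "L3")), directed = TRUE)
  s <- list(graph = star, perturbed_nodes = character(), treatment = "t",
            parent_hash = "h")
  class(s) <- "subnetwork"
  ct <- centralities(s)
  expect_equal(ct$degree_centrality[ct$node == "HUB"], 1)
  expect_equal(ct$degree_centrality[ct$node != "HUB"], rep(1 / 3, 3))
  expect_equal(ct$eigenvector_centrality[ct$node == "HUB"], 1)

  tri <- igraph::graph_from_edgelist(cbind(c("A", "B", "C"), c("B", "C", "A")))
  s$graph <- tri
  ct <- centralities(s)
  expect_equal(ct$eigenvector_centrality, rep(1, 3), tolerance = 1e-9)

  one <- igraph::set_vertex_attr(igraph::make_empty_graph(1), "name", value = "Z")
  s$graph <- one
  ct <- centralities(s)
  expect_equal(ct$degree_centrality, 0)
  expect_equal(ct$eigenvector_centrality, 1)

  # random graphs against a dense eigendecomposition
  for (seed in 1:10) {
    set.seed(seed)
    n <- 6
    repeat {
      A <- matrix(rbinom(n * n, 1, 0.5), n)
      A[lower.tri(A)] <- t(A)[lower.tri(A)]
      diag(A) <- 0
      if (oracle_connected(which(A == 1, arr.ind = TRUE), n)) break
    }
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    igraph::V(g)$name <- sprintf("V%d", 1:n)
    s$graph <- g
    ct <- centralities(s)
    ev <- eigen(A)$vectors[, 1]
    ev <- abs(ev) / max(abs(ev))
    expect_equal(ct$eigenvector_centrality, ev, tolerance = 1e-8)
    expect_equal(ct$degree_centrality, rowSums(A) / (n - 1))
  }
})

test_that("mutation overrepresentation follows the two-sided exact convention", {
  prior <- gen_prior_network(4, 4, 0.5, seed = 1)
  vn <- igraph::V(prior)$name
  sub_nodes <- vn[1:4]
  g <- igraph::induced_subgraph(prior, sub_nodes)
  s <- structure(list(graph = g, perturbed_nodes = sub_nodes, treatment = "t",
                      parent_hash = "h"), class = "subnetwork")
  # [[3,1],[1,3]] layout: 3 of 4 subnetwork nodes mutated, 1 of 4 background
  muts <- c(sub_nodes[1:3], vn[5])
  fr <- mutation_enrichment(s, prior, muts)
  expect_equal(unname(fr$table[1, ]), c(3, 1))
  expect_equal(unname(fr$table[2, ]), c(1, 3))
  expect_equal(fr$p, 34 / 70, tolerance = 1e-12)
  expect_equal(fr$p, oracle_fisher(fr$table), tolerance = 1e-12)
  # extreme diagonal table: two-sided p doubles the single tail
  fr2 <- mutation_enrichment(s, prior, sub_nodes)
  expect_equal(fr2$p, 2 / choose(8, 4), tolerance = 1e-12)
  expect_equal(fr2$p, oracle_fisher(fr2$table), tolerance = 1e-12)
  # no mutations anywhere
  fr3 <- mutation_enrichment(s, prior, character())
  expect_equal(fr3$p, 1)
  # Fisher p invariant under swapping both rows and both columns
  tab <- matrix(c(5, 2, 3, 7), 2)
  swapped <- tab[2:1, 2:1]
  expect_equal(fisher.test(tab)$p.value, fisher.test(swapped)$p.value)
  # degenerate background
  full <- structure(list(graph = prior, perturbed_nodes = vn, treatment = "t",
                         parent_hash = "h"), class = "subnetwork")
  expect_error(mutation_enrichment(full, prior, muts), "background")
})
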