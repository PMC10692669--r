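# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately use naive algorithms (explicit loops,
# exhaustive enumeration, BFS) and share no code with the package internals.

# Straightforward running-sum enrichment area: walk the ranking position by
# position, accumulate the running statistic, and average it.
oracle_area_es <- function(scores, member_sites, directions, weight = 1) {
  ord <- order(-scores, names(scores))
  s <- scores[ord]
  is_mem <- names(s) %in% member_sites
  dir_of <- stats::setNames(directions, member_sites)
  n <- length(s)
  m <- sum(is_mem)
  nr <- sum(abs(s[is_mem])^weight)
  tot <- 0
  for (i in which(is_mem)) {
    dsgn <- if (dir_of[[names(s)[i]]] == "d") -1 else 1
    tot <- tot + dsgn * abs(s[i])^weight / nr
  }
  run <- 0
  area <- 0
  for (i in seq_len(n)) {
    if (is_mem[i]) {
      dsgn <- if (dir_of[[names(s)[i]]] == "d") -1 else 1
      run <- run + dsgn * abs(s[i])^weight / nr
    } else {
      run <- run - tot / (n - m)
    }
    area <- area + run
  }
  unname(area / n)
}

# BFS connectivity check on an undirected edge list over vertices 1..n
oracle_connected <- function(edges, n) {
  if (n <= 1) return(TRUE)
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  seen <- logical(n); seen[1] <- TRUE; queue <- 1
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  all(seen)
}

# Exhaustive subnetwork extraction on a small directed annotated graph.
# `ed` is a data.frame(from, to, edge_fdr); `nodes` a data.frame(name, nes,
# node_fdr). Returns list(nodes, edges) with edges as "from>to" keys.
oracle_extract <- function(nodes, ed, node_fdr = 0.05, edge_fdr = 0.05,
                           max_len = 2) {
  vn <- nodes$name
  pert_n <- vn[!is.na(nodes$node_fdr) & nodes$node_fdr <= node_fdr]
  pert_e <- which(!is.na(ed$edge_fdr) & ed$edge_fdr <= edge_fdr)
  if (!length(pert_n) && !length(pert_e)) return(list(nodes = character(), edges = character()))
  ekey <- paste(ed$from, ed$to, sep = ">")
  # enumerate all directed paths of length <= max_len between perturbed pairs,
  # keep only those of minimal length per ordered pair
  path_edges <- character()
  for (u in pert_n) for (v in pert_n) {
    if (u == v) next
    paths1 <- list()
    if (paste(u, v, sep = ">") %in% ekey) paths1 <- list(c(u, v))
    paths2 <- list()
    for (w in vn) {
      if (w != u && w != v &&
          paste(u, w, sep = ">") %in% ekey && paste(w, v, sep = ">") %in% ekey) {
        paths2[[length(paths2) + 1]] <- c(u, w, v)
      }
    }
    chosen <- if (length(paths1)) paths1 else if (max_len >= 2) paths2 else list()
    for (p in chosen) {
      for (k in seq_len(length(p) - 1)) {
        path_edges <- c(path_edges, paste(p[k], p[k + 1], sep = ">"))
      }
    }
  }
  cand_e <- sort(unique(c(ekey[pert_e], path_edges)))
  ends <- unlist(strsplit(cand_e, ">", fixed = TRUE))
  cand_v <- sort(unique(c(pert_n, ends)))
  # undirected components by BFS over candidate edges
  idx <- stats::setNames(seq_along(cand_v), cand_v)
  em <- do.call(rbind, lapply(strsplit(cand_e, ">", fixed = TRUE),
                              function(p) c(idx[[p[1]]], idx[[p[2]]])))
  comp <- rep(NA_integer_, length(cand_v)); cc <- 0
  for (s in seq_along(cand_v)) {
    if (!is.na(comp[s])) next
    cc <- cc + 1; comp[s] <- cc; queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.null(em)) {
        nb <- c(em[em[, 1] == v, 2], em[em[, 2] == v, 1])
        for (w in nb) if (is.na(comp[w])) { comp[w] <- cc; queue <- c(queue, w) }
      }
    }
  }
  # best component: size, then total |NES|, then lexicographic node set
  best <- NULL
  for (ci in seq_len(cc)) {
    nds <- sort(cand_v[comp == ci])
    tn <- sum(abs(nodes$nes[match(nds, nodes$name)]), na.rm = TRUE)
    cand <- list(size = length(nds), tot = tn, nodes = nds)
    if (is.null(best) || cand$size > best$size ||
        (cand$size == best$size && cand$tot > best$tot) ||
        (cand$size == best$size && cand$tot == best$tot &&
         paste(cand$nodes, collapse = ",") < paste(best$nodes, collapse = ","))) {
      best <- cand
    }
  }
  keep_e <- cand_e[vapply(strsplit(cand_e, ">", fixed = TRUE),
                          function(p) all(p %in% best$nodes), logical(1))]
  list(nodes = best$nodes, edges = sort(keep_e))
}

# Two-sided Fisher p by enumeration of all 2x2 tables with the observed margins
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  prob <- function(a) dhyper(a, r1, r2, c1)
  p_obs <- prob(tab[1, 1])
  ks <- max(0, c1 - r2):min(r1, c1)
  sum(vapply(ks, prob, numeric(1))[vapply(ks, prob, numeric(1)) <= p_obs * (1 + 1e-7)])
}

# Random annotated graph generator for oracle-equivalence sweeps
random_annotated_graph <- function(seed, n_nodes = NULL) {
  set.seed(seed)
  n <- if (is.null(n_nodes)) sample(5:30, 1) else n_nodes
  vn <- sprintf("N%02d", seq_len(n))
  ne <- sample(n:(3 * n), 1)
  from <- sample(vn, ne, replace = TRUE)
  to <- sample(vn, ne, replace = TRUE)
  keep <- from != to & !duplicated(paste(from, to))
  from <- from[keep]; to <- to[keep]
  nes <- ifelse(runif(n) < 0.5, rnorm(n, 0, 2), NA)
  node_fdr <- ifelse(is.na(nes), NA, runif(n)^2)
  edge_fdr <- ifelse(runif(length(from)) < 0.6, runif(length(from))^2, NA)
  nodes <- data.frame(name = vn, nes = nes, node_fdr = node_fdr,
                      stringsAsFactors = FALSE)
  ed <- data.frame(from = from, to = to, sign = 1L, mechanism = "phosphorylation",
                   residues = "S1", log2fc = ifelse(is.na(edge_fdr), NA, rnorm(length(from))),
                   edge_fdr = edge_fdr, site = NA_character_,
                   stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(ed, directed = TRUE, vertices = nodes)
  attr(g, "treatment") <- "trt"
  attr(g, "parent_hash") <- "h"
  class(g) <- c("annotated_network", class(g))
  list(graph = g, nodes = nodes, edges = ed)
}

subnetwork_as_sets <- function(s) {
  ed <- igraph::as_data_frame(s$graph, what = "edges")
  list(nodes = sort(igraph::V(s$graph)$name),
       edges = sort(paste(ed$from, ed$to, sep = ">")))
}

# Voronoi adjacency via the external scipy/shapely oracle script
oracle_voronoi <- function(x, y, frame) {
  pf <- tempfile(fileext = ".csv"); of <- tempfile(fileext = ".csv")
  on.exit(unlink(c(pf, of)))
  utils::write.csv(data.frame(x = x, y = y), pf, row.names = FALSE)
  script <- system.file("oracles", "voronoi_oracle.py", package = "phosnet")
  status <- system2("python", c(script, pf, as.character(frame[1]),
                                as.character(frame[2]), of))
  stopifnot(status == 0)
  as.matrix(utils::read.csv(of))
}

random_cell_map <- function(seed, n = 80, frame = c(1000, 1000)) {
  set.seed(seed)
  as_cell_map(data.frame(cell_id = sprintf("c%04d", seq_len(n)), roi_id = "r1",
                         x_um = runif(n, 0, frame[1]), y_um = runif(n, 0, frame[2]),
                         phenotype = sample(c("a", "b"), n, replace = TRUE),
                         stringsAsFactors = FALSE), frame)
}
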