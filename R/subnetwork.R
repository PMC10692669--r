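#' Load a prior causal signaling network from a SIGNOR-style TSV
#'
#' Expects tab-separated columns \code{ENTITYA}, \code{ENTITYB},
#' \code{EFFECT}, \code{MECHANISM}, \code{RESIDUE}. Effects are parsed as
#' +1 for values starting with \code{"up-regulates"} (or numeric > 0) and -1
#' for \code{"down-regulates"} (or numeric < 0). Self-loops are dropped (with
#' a message of the count); duplicate ordered edges are merged with their
#' residue annotations unioned, keeping the first row's sign and mechanism.
#'
#' @param path Path to the TSV file.
#' @return A \code{prior_network} (directed \pkg{igraph} graph; see
#'   \code{\link{gen_prior_network}} for the attribute schema).
#' @export
load_prior <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("ENTITYA", "ENTITYB", "EFFECT", "MECHANISM", "RESIDUE")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("prior network file lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (nrow(df) == 0) stopf("prior network file has zero edges")
  sgn <- ifelse(grepl("^down-regulates", df$EFFECT) |
                  suppressWarnings(as.numeric(df$EFFECT)) < 0, -1L, 1L)
  sgn[is.na(sgn)] <- 1L
  loops <- df$ENTITYA == df$ENTITYB
  if (any(loops)) {
    message(sprintf("dropped %d self-loop(s)", sum(loops)))
    df <- df[!loops, , drop = FALSE]
    sgn <- sgn[!loops]
  }
  if (nrow(df) == 0) stopf("prior network has zero edges after dropping self-loops")
  key <- paste(df$ENTITYA, df$ENTITYB, sep = "\r")
  residues <- tapply(df$RESIDUE, key, function(r) {
    paste(unique(unlist(strsplit(r[r != "" & !is.na(r)], ",", fixed = TRUE))),
          collapse = ",")
  })
  first <- !duplicated(key)
  ed <- data.frame(from = df$ENTITYA[first], to = df$ENTITYB[first],
                   sign = sgn[first], mechanism = df$MECHANISM[first],
                   residues = as.character(residues[key[first]]),
                   stringsAsFactors = FALSE)
  bad <- ed$residues != "" &
    !vapply(strsplit(ed$residues, ",", fixed = TRUE),
            function(r) all(grepl("^[A-Z][0-9]+$", r)), logical(1))
  if (any(bad)) stopf("syntactically invalid residue annotation(s), e.g. '%s'",
                      ed$residues[bad][1])
  g <- igraph::graph_from_data_frame(ed, directed = TRUE)
  class(g) <- c("prior_network", class(g))
  g
}

#' Write a prior network as a SIGNOR-style TSV
#' @param net A \code{prior_network}.
#' @param path Output path.
#' @export
write_signor <- function(net, path) {
  ed <- igraph::as_data_frame(net, what = "edges")
  out <- data.frame(ENTITYA = ed$from, ENTITYB = ed$to,
                    EFFECT = ifelse(ed$sign > 0, "up-regulates", "down-regulates"),
                    MECHANISM = ed$mechanism, RESIDUE = ed$residues,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

parent_hash <- function(net) {
  ed <- igraph::as_data_frame(net, what = "edges")
  key <- paste(ed$from, ed$to, sep = ">")
  paste(sort(key), collapse = "|")
}

#' Annotate a prior network with activities and phosphosite fold changes
#'
#' Maps kinase-signature normalized enrichment scores (and their FDR) to
#' nodes, and phosphosite log2 fold changes (and their FDR) to the edges whose
#' residue annotations match a measured site on the target protein. When an
#' edge carries several measured residues, the site with the smallest FDR
#' represents the edge. Unannotated attributes are NA, never zero.
#'
#' @param prior A \code{prior_network}.
#' @param enrichment An \code{enrichment_result} whose signature names are
#'   node symbols (kinase signatures).
#' @param diff A collapsed \code{diff_table} for one treatment.
#' @param treatment Treatment label stored on the result.
#' @return An \code{annotated_network}: the graph with node attributes
#'   \code{nes}, \code{node_fdr} and edge attributes \code{log2fc},
#'   \code{edge_fdr}, \code{site}.
#' @export
annotate_network <- function(prior, enrichment, diff, treatment = unique(diff$treatment)[1]) {
  g <- prior
  idx <- match(igraph::V(g)$name, enrichment$signature)
  igraph::V(g)$nes <- enrichment$nes[idx]
  igraph::V(g)$node_fdr <- enrichment$fdr[idx]
  ed <- igraph::as_data_frame(g, what = "edges")
  site_key <- paste(diff$protein, paste0(diff$residue, diff$position))
  lfc <- fdr <- rep(NA_real_, nrow(ed))
  best_site <- rep(NA_character_, nrow(ed))
  for (i in seq_len(nrow(ed))) {
    res <- strsplit(ed$residues[i], ",", fixed = TRUE)[[1]]
    hit <- which(site_key %in% paste(ed$to[i], res))
    if (!length(hit)) next
    j <- hit[which.min(diff$fdr[hit])]
    lfc[i] <- diff$log2fc[j]
    fdr[i] <- diff$fdr[j]
    best_site[i] <- site_id(diff$protein[j], diff$residue[j], diff$position[j])
  }
  igraph::E(g)$log2fc <- lfc
  igraph::E(g)$edge_fdr <- fdr
  igraph::E(g)$site <- best_site
  attr(g, "treatment") <- treatment
  attr(g, "parent_hash") <- parent_hash(prior)
  class(g) <- unique(c("annotated_network", class(g)))
  g
}

# ordered-pair key for path bookkeeping
pair_key <- function(u, v) paste(u, v, sep = " -> ")

#' Extract a perturbation subnetwork
#'
#' Perturbed nodes are those with kinase-signature FDR at most
#' \code{node_fdr}; perturbed edges those with phosphosite FDR at most
#' \code{edge_fdr} (both thresholds inclusive). For every ordered pair of
#' distinct perturbed nodes whose shortest directed path length is at most
#' \code{max_path_len} hops, all shortest paths are collected; the union of
#' their edges with the perturbed edges (plus endpoints and the perturbed
#' nodes themselves) forms a candidate graph, and the largest connected
#' component under undirected connectivity is returned. Component-size ties
#' are broken by larger total |NES|, then by the lexicographically smallest
#' sorted node-name vector. Per-element provenance records whether an element
#' entered as \code{perturbed_node}, \code{perturbed_edge} or
#' \code{path_connector} (perturbed status takes precedence).
#'
#' @param a An \code{annotated_network}.
#' @param node_fdr,edge_fdr Inclusive FDR gates (default 0.05).
#' @param max_path_len Maximum shortest-path length in edges (default 2).
#' @param directed Compute shortest paths on the directed graph over ordered
#'   pairs (default, the causal reading); \code{FALSE} uses undirected paths.
#' @return A \code{subnetwork} object: list with \code{graph} (the component,
#'   with \code{provenance} vertex/edge attributes), \code{paths} (retained
#'   shortest paths per ordered perturbed pair), \code{perturbed_nodes},
#'   \code{treatment}, \code{parent_hash}. Empty annotation yields an empty
#'   subnetwork with a warning.
#' @export
extract_subnetwork <- function(a, node_fdr = 0.05, edge_fdr = 0.05,
                               max_path_len = 2, directed = TRUE) {
  vn <- igraph::V(a)$name
  nf <- igraph::V(a)$node_fdr
  pert_nodes <- vn[!is.na(nf) & nf <= node_fdr]
  ef <- igraph::E(a)$edge_fdr
  pert_eids <- which(!is.na(ef) & ef <= edge_fdr)
  ed <- igraph::as_data_frame(a, what = "edges")
  if (!length(pert_nodes) && !length(pert_eids)) {
    warnf("no perturbed nodes or edges at the given FDR gates; empty subnetwork")
    g0 <- igraph::induced_subgraph(a, integer())
    return(structure(list(graph = g0, paths = list(),
                          perturbed_nodes = character(),
                          treatment = attr(a, "treatment"),
                          parent_hash = attr(a, "parent_hash")),
                     class = "subnetwork"))
  }
  mode <- if (directed) "out" else "all"
  paths <- list()
  path_edges <- character()
  if (length(pert_nodes) >= 2) {
    dm <- igraph::distances(a, v = pert_nodes, to = pert_nodes, mode = mode)
    for (u in pert_nodes) for (v in pert_nodes) {
      if (u == v) next
      if (!is.finite(dm[u, v]) || dm[u, v] > max_path_len) next
      sp <- igraph::all_shortest_paths(a, from = u, to = v, mode = mode)
      vp <- lapply(sp$vpaths, function(p) igraph::V(a)$name[as.integer(p)])
      paths[[pair_key(u, v)]] <- vp
      for (p in vp) {
        if (length(p) > 1) {
          path_edges <- c(path_edges, paste(p[-length(p)], p[-1], sep = "\r"))
        }
      }
    }
  }
  edge_key <- paste(ed$from, ed$to, sep = "\r")
  # undirected path search may traverse edges against their direction
  if (!directed) {
    rev_key <- paste(ed$to, ed$from, sep = "\r")
    path_edges <- unique(c(
      path_edges[path_edges %in% edge_key],
      edge_key[rev_key %in% path_edges]
    ))
  }
  cand_eids <- sort(unique(c(pert_eids, which(edge_key %in% path_edges))))
  cand_vs <- unique(c(pert_nodes, ed$from[cand_eids], ed$to[cand_eids]))
  g <- igraph::induced_subgraph(a, cand_vs)
  ge <- igraph::as_data_frame(g, what = "edges")
  keep <- paste(ge$from, ge$to, sep = "\r") %in% edge_key[cand_eids]
  g <- igraph::delete_edges(g, which(!keep))

  comp <- igraph::components(igraph::as_undirected(g, mode = "collapse"))
  best <- NULL
  for (ci in seq_len(comp$no)) {
    nodes <- sort(igraph::V(g)$name[comp$membership == ci])
    nes <- igraph::V(g)$nes[comp$membership == ci]
    score <- list(size = length(nodes),
                  tot_nes = sum(abs(nes), na.rm = TRUE),
                  nodes = nodes)
    if (is.null(best) ||
        score$size > best$size ||
        (score$size == best$size && score$tot_nes > best$tot_nes) ||
        (score$size == best$size && score$tot_nes == best$tot_nes &&
         paste(score$nodes, collapse = "\r") < paste(best$nodes, collapse = "\r"))) {
      best <- score
    }
  }
  gg <- igraph::induced_subgraph(g, best$nodes)
  igraph::V(gg)$provenance <- ifelse(igraph::V(gg)$name %in% pert_nodes,
                                     "perturbed_node", "path_connector")
  gge <- igraph::as_data_frame(gg, what = "edges")
  pert_edge_key <- edge_key[pert_eids]
  igraph::E(gg)$provenance <- ifelse(paste(gge$from, gge$to, sep = "\r") %in% pert_edge_key,
                                     "perturbed_edge", "path_connector")
  keep_nodes <- igraph::V(gg)$name
  paths <- lapply(paths, function(vp) Filter(function(p) all(p %in% keep_nodes), vp))
  paths <- paths[vapply(paths, length, integer(1)) > 0]
  structure(list(graph = gg, paths = paths,
                 perturbed_nodes = intersect(pert_nodes, keep_nodes),
                 treatment = attr(a, "treatment"),
                 parent_hash = attr(a, "parent_hash")),
            class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf("<subnetwork> %d nodes, %d edges%s\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              if (!is.null(x$treatment) && !is.na(x$treatment))
                paste0(" (treatment: ", x$treatment, ")") else ""))
  invisible(x)
}

path_edge_keys <- function(p) {
  if (length(p) < 2) return(character())
  paste(p[-length(p)], p[-1], sep = "\r")
}

#' Prune redundant shortest paths from a subnetwork
#'
#' For each perturbed-node pair connected by several shortest paths, paths
#' whose every edge carries a measured phosphosite (non-missing edge log2FC)
#' are preferred: when at least one fully annotated path exists, unannotated
#' alternatives are removed, provided their edges and connector nodes serve no
#' other retained path and are not themselves perturbed. Removal that would
#' disconnect the subnetwork is rolled back for that pair, so connectivity is
#' preserved. The exact pruning predicate of the published analysis is not
#' fully specified; this is the package's documented reading.
#'
#' @param s A \code{subnetwork} from \code{\link{extract_subnetwork}} with
#'   path provenance intact.
#' @return A pruned \code{subnetwork}.
#' @export
prune_redundant_paths <- function(s) {
  stopifnot(inherits(s, "subnetwork"))
  g <- s$graph
  paths <- s$paths
  if (!length(paths)) return(s)
  is_annotated <- function(p) {
    ek <- path_edge_keys(p)
    ed <- igraph::as_data_frame(g, what = "edges")
    key <- paste(ed$from, ed$to, sep = "\r")
    idx <- match(ek, key)
    length(idx) > 0 && !anyNA(idx) && all(!is.na(ed$log2fc[idx]))
  }
  for (pk in sort(names(paths))) {
    vp <- paths[[pk]]
    if (length(vp) < 2) next
    ann <- vapply(vp, is_annotated, logical(1))
    if (!any(ann) || all(ann)) next
    keep_paths <- vp[ann]
    other_paths <- c(unlist(paths[setdiff(names(paths), pk)], recursive = FALSE),
                     keep_paths)
    protected_edges <- unique(unlist(lapply(other_paths, path_edge_keys)))
    protected_nodes <- unique(unlist(other_paths))
    ed <- igraph::as_data_frame(g, what = "edges")
    key <- paste(ed$from, ed$to, sep = "\r")
    drop_e <- integer()
    drop_v <- character()
    for (p in vp[!ann]) {
      ek <- path_edge_keys(p)
      idx <- match(ek, key)
      idx <- idx[!is.na(idx)]
      idx <- idx[igraph::E(g)$provenance[idx] != "perturbed_edge" &
                   !(key[idx] %in% protected_edges)]
      drop_e <- union(drop_e, idx)
      interior <- p[-c(1, length(p))]
      interior <- interior[!(interior %in% s$perturbed_nodes) &
                             !(interior %in% protected_nodes)]
      drop_v <- union(drop_v, interior)
    }
    if (!length(drop_e) && !length(drop_v)) next
    g2 <- igraph::delete_edges(g, drop_e)
    # drop candidate connector nodes only if they became isolated
    deg <- igraph::degree(g2, mode = "all")
    iso <- drop_v[drop_v %in% igraph::V(g2)$name[deg == 0]]
    g2 <- igraph::delete_vertices(g2, iso)
    if (igraph::vcount(g2) > 0 &&
        igraph::components(igraph::as_undirected(g2, mode = "collapse"))$no == 1) {
      g <- g2
      paths[[pk]] <- keep_paths
    }
  }
  structure(list(graph = g, paths = paths, perturbed_nodes = s$perturbed_nodes,
                 treatment = s$treatment, parent_hash = s$parent_hash),
            class = "subnetwork")
}

#' Merge treatment subnetworks into a per-sample network
#'
#' Node and edge union over subnetworks that share one parent prior network.
#' Per-treatment annotations are kept side by side as \code{nes_<treatment>},
#' \code{log2fc_<treatment>} etc., never averaged; \code{n_subgraphs} counts,
#' per node, the input subnetworks containing it.
#'
#' @param subs List of \code{subnetwork} objects.
#' @return A merged \code{subnetwork} (its \code{paths} are dropped;
#'   provenance per treatment is kept as \code{provenance_<treatment>}).
#' @export
merge_subnetworks <- function(subs) {
  stopifnot(length(subs) >= 1, all(vapply(subs, inherits, logical(1), "subnetwork")))
  ph <- unique(vapply(subs, function(s) s$parent_hash %||% "", character(1)))
  if (length(ph) != 1) stopf("subnetworks derive from different parent networks")
  trts <- vapply(seq_along(subs), function(i) {
    tr <- subs[[i]]$treatment
    if (is.null(tr) || is.na(tr)) paste0("subnetwork", i) else tr
  }, character(1))
  all_nodes <- sort(unique(unlist(lapply(subs, function(s) igraph::V(s$graph)$name))))
  vdf <- data.frame(name = all_nodes, stringsAsFactors = FALSE)
  vdf$n_subgraphs <- 0L
  eds <- list()
  for (i in seq_along(subs)) {
    g <- subs[[i]]$graph
    tr <- trts[i]
    nm <- igraph::V(g)$name
    vdf$n_subgraphs <- vdf$n_subgraphs + as.integer(vdf$name %in% nm)
    vdf[[paste0("nes_", tr)]] <- igraph::V(g)$nes[match(vdf$name, nm)]
    vdf[[paste0("node_fdr_", tr)]] <- igraph::V(g)$node_fdr[match(vdf$name, nm)]
    vdf[[paste0("provenance_", tr)]] <- igraph::V(g)$provenance[match(vdf$name, nm)]
    ed <- igraph::as_data_frame(g, what = "edges")
    if (nrow(ed)) {
      ed$treatment <- tr
      eds[[i]] <- ed
    }
  }
  ed_all <- do.call(rbind, eds)
  edge_cols <- c("sign", "mechanism", "residues")
  if (is.null(ed_all)) {
    ed_un <- data.frame(from = character(), to = character())
  } else {
    key <- paste(ed_all$from, ed_all$to, sep = "\r")
    ed_un <- ed_all[!duplicated(key), c("from", "to", intersect(edge_cols, names(ed_all))), drop = FALSE]
    for (tr in unique(ed_all$treatment)) {
      sub <- ed_all[ed_all$treatment == tr, , drop = FALSE]
      m <- match(paste(ed_un$from, ed_un$to, sep = "\r"),
                 paste(sub$from, sub$to, sep = "\r"))
      if ("log2fc" %in% names(sub)) ed_un[[paste0("log2fc_", tr)]] <- sub$log2fc[m]
      if ("edge_fdr" %in% names(sub)) ed_un[[paste0("edge_fdr_", tr)]] <- sub$edge_fdr[m]
      if ("provenance" %in% names(sub)) ed_un[[paste0("provenance_", tr)]] <- sub$provenance[m]
    }
  }
  g <- igraph::graph_from_data_frame(ed_un, directed = TRUE, vertices = vdf)
  structure(list(graph = g, paths = list(),
                 perturbed_nodes = sort(unique(unlist(lapply(subs, `[[`, "perturbed_nodes")))),
                 treatment = NA_character_, parent_hash = ph),
            class = "subnetwork")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Node centralities of a subnetwork
#'
#' Degree and eigenvector centrality on the undirected simple projection of
#' the subnetwork. Degree centrality is degree/(n-1); eigenvector centrality
#' is computed by power iteration on the adjacency matrix to an infinity-norm
#' tolerance of 1e-10 and max-normalized to 1. A single-node graph gets degree
#' 0 and eigenvector 1 by convention; in a disconnected graph the eigenvector
#' concentrates on the dominant component (other components approach 0).
#'
#' @param s A \code{subnetwork} (or an igraph graph).
#' @return A data.frame: \code{node}, \code{degree_centrality},
#'   \code{eigenvector_centrality}, \code{n_subgraphs} (1 when the input is a
#'   single-treatment subnetwork).
#' @export
centralities <- function(s) {
  g <- if (inherits(s, "subnetwork")) s$graph else s
  if (igraph::vcount(g) == 0) stopf("empty subnetwork")
  u <- igraph::simplify(igraph::as_undirected(g, mode = "collapse"))
  n <- igraph::vcount(u)
  deg <- igraph::degree(u)
  dc <- if (n > 1) deg / (n - 1) else 0
  A <- igraph::as_adjacency_matrix(u, sparse = FALSE)
  if (n == 1) {
    ec <- 1
  } else if (sum(A) == 0) {
    ec <- rep(0, n)
  } else {
    # shifted power iteration: A + I has the same eigenvectors but a strictly
    # dominant eigenvalue on connected (incl. bipartite) graphs, so the
    # iteration cannot oscillate
    M <- A + diag(n)
    x <- rep(1, n)
    repeat {
      xn <- as.vector(M %*% x)
      if (max(xn) == 0) { x <- rep(0, n); break }
      xn <- xn / max(xn)
      if (max(abs(xn - x)) < 1e-10) { x <- xn; break }
      x <- xn
    }
    ec <- x
  }
  ns <- igraph::V(g)$n_subgraphs
  if (is.null(ns)) ns <- rep(1L, n)
  data.frame(node = igraph::V(u)$name, degree_centrality = dc,
             eigenvector_centrality = ec, n_subgraphs = ns,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Mutation overrepresentation in a subnetwork
#'
#' Two-sided Fisher's exact test of whether coding mutations are enriched
#' among subnetwork nodes relative to the rest of the prior network. The
#' two-sided p sums the probabilities of all tables (at fixed margins) whose
#' point probability does not exceed the observed table's.
#'
#' @param s A \code{subnetwork}.
#' @param prior The parent \code{prior_network}.
#' @param mutated_genes Character vector of mutated gene symbols (same
#'   namespace as the network nodes).
#' @return A \code{fisher_result} list: \code{table} (2x2 counts),
#'   \code{odds_ratio}, \code{p}.
#' @export
mutation_enrichment <- function(s, prior, mutated_genes) {
  sub_nodes <- igraph::V(s$graph)$name
  bg <- setdiff(igraph::V(prior)$name, sub_nodes)
  if (!length(bg)) stopf("subnetwork equals the prior network; background is empty")
  tab <- matrix(c(sum(sub_nodes %in% mutated_genes),
                  sum(!(sub_nodes %in% mutated_genes)),
                  sum(bg %in% mutated_genes),
                  sum(!(bg %in% mutated_genes))),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("subnetwork", "background"),
                                c("mutated", "non_mutated")))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  structure(list(table = tab, odds_ratio = unname(ft$estimate), p = ft$p.value),
            class = "fisher_result")
}

#' @export
print.fisher_result <- function(x, ...) {
  cat("<fisher_result> two-sided Fisher's exact test\n")
  print(x$table)
  cat(sprintf("odds ratio %.4g, p = %.4g\n", x$odds_ratio, x$p))
  invisible(x)
}

#' Export a subnetwork as GraphML plus a flat edge-list CSV
#'
#' @param s A \code{subnetwork}.
#' @param graphml_path,csv_path Output paths (either may be NULL to skip).
#' @return Invisibly, the paths written.
#' @export
write_subnetwork <- function(s, graphml_path = NULL, csv_path = NULL) {
  if (!is.null(graphml_path)) {
    igraph::write_graph(s$graph, graphml_path, format = "graphml")
  }
  if (!is.null(csv_path)) {
    ed <- igraph::as_data_frame(s$graph, what = "edges")
    write.csv(ed, csv_path, row.names = FALSE)
  }
  invisible(c(graphml_path, csv_path))
}
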