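#' Construct a spatial cell map
#'
#' A segmented-cell table for one or more regions of interest: cell ids,
#' centroid coordinates in micrometres, a phenotype label, and optional
#' per-marker positive-area fractions in [0, 1]. The ROI frame (width, height
#' in micrometres) is stored as an attribute and bounds all coordinates.
#'
#' @param df data.frame with columns \code{cell_id}, \code{roi_id},
#'   \code{x_um}, \code{y_um}, \code{phenotype}, plus one numeric column per
#'   marker.
#' @param frame_um c(width, height) of the ROI frame in micrometres.
#' @return A \code{cell_map} data.frame.
#' @export
as_cell_map <- function(df, frame_um) {
  need <- c("cell_id", "roi_id", "x_um", "y_um", "phenotype")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("cell table lacks column(s): %s", paste(miss, collapse = ", "))
  if (any(df$x_um < 0 | df$x_um > frame_um[1] | df$y_um < 0 | df$y_um > frame_um[2])) {
    stopf("cell coordinates outside the ROI frame")
  }
  markers <- setdiff(names(df), need)
  for (m in markers) {
    if (is.numeric(df[[m]]) && any(df[[m]] < 0 | df[[m]] > 1, na.rm = TRUE)) {
      stopf("marker '%s' has positive-area fractions outside [0, 1]", m)
    }
  }
  structure(df, frame_um = as.numeric(frame_um),
            class = c("cell_map", "data.frame"))
}

#' @export
print.cell_map <- function(x, ...) {
  f <- attr(x, "frame_um")
  cat(sprintf("<cell_map> %d cells, %d phenotype(s), frame %g x %g um\n",
              nrow(x), length(unique(x$phenotype)), f[1], f[2]))
  invisible(x)
}

#' Marker positivity calls
#'
#' A cell is positive for a marker when the marker was positively detected in
#' at least \code{threshold} of its area (inclusive: exactly the threshold is
#' positive).
#'
#' @param c A \code{cell_map}.
#' @param marker Marker column name.
#' @param threshold Positive-area fraction threshold (default 0.10).
#' @return Logical vector, one entry per cell.
#' @export
marker_positive <- function(c, marker, threshold = 0.10) {
  if (!marker %in% names(c)) stopf("unknown marker '%s'", marker)
  c[[marker]] >= threshold
}

#' Per-phenotype cell densities
#'
#' Counts per phenotype divided by the ROI frame area, in cells per square
#' millimetre (1 mm^2 = 1e6 um^2). Phenotypes can be supplied to include
#' zero-count entries.
#'
#' @param c A \code{cell_map} (one ROI).
#' @param phenotypes Optional phenotype catalog; defaults to those present.
#' @return Named numeric vector of densities (cells/mm^2).
#' @export
densities <- function(c, phenotypes = NULL) {
  f <- attr(c, "frame_um")
  area_mm2 <- f[1] * f[2] / 1e6
  if (area_mm2 <= 0) stopf("zero-area ROI frame")
  if (is.null(phenotypes)) phenotypes <- sort(unique(c$phenotype))
  cnt <- table(factor(c$phenotype, levels = phenotypes))
  as.numeric(cnt) / area_mm2 -> d
  stats::setNames(d, phenotypes)
}

#' Voronoi neighborhood graph of a cell map
#'
#' Computes the Voronoi tessellation of the cell centroids, clips every cell
#' to the ROI frame, and connects two cells when their clipped polygons share
#' a boundary segment of positive length (point contacts are excluded, so
#' diagonal lattice neighbors do not count). Duplicate coordinates are
#' jittered by 1e-6 um with a seeded RNG; fewer than 3 cells or an entirely
#' collinear configuration is an error.
#'
#' @param c A \code{cell_map} for a single ROI.
#' @param min_boundary_um Minimum shared-boundary length for an edge
#'   (default 1e-6 um, i.e. positive length up to numerical noise).
#' @param jitter_seed Seed for the duplicate-coordinate jitter.
#' @return A \code{neighbor_graph}: list with \code{edges} (2-column matrix of
#'   cell indices, each unordered pair once), \code{cell_id}, \code{n},
#'   \code{polygons} (clipped Voronoi cells, one matrix of vertices per cell)
#'   and the frame.
#' @export
voronoi_neighbors <- function(c, min_boundary_um = 1e-6, jitter_seed = 1) {
  f <- attr(c, "frame_um")
  n <- nrow(c)
  if (n < 3) stopf("Voronoi neighborhood needs >= 3 cells, got %d", n)
  x <- c$x_um; y <- c$y_um
  if (anyDuplicated(cbind(x, y))) {
    dup <- duplicated(cbind(x, y))
    with_seed(jitter_seed, {
      x[dup] <- x[dup] + runif(sum(dup), -1e-6, 1e-6)
      y[dup] <- y[dup] + runif(sum(dup), -1e-6, 1e-6)
    })
    message(sprintf("jittered %d duplicate coordinate(s) by 1e-6 um (seed %d)",
                    sum(dup), jitter_seed))
  }
  # collinearity: all points on one line make the tessellation degenerate
  if (n >= 3) {
    dx <- x - x[1]; dy <- y - y[1]
    cross <- dx[2] * dy - dy[2] * dx
    if (all(abs(cross) < 1e-12)) {
      stopf("all cells are collinear; Voronoi adjacency is degenerate (spread the points or add cells)")
    }
  }
  cells <- voronoi_cells_cpp(x, y, 0, f[1], 0, f[2])
  edges <- voronoi_adjacency_cpp(cells$polygons, cells$owners, min_boundary_um)
  stopifnot(all(edges[, 1] < edges[, 2]))
  structure(list(edges = edges, cell_id = c$cell_id, n = n,
                 polygons = cells$polygons, frame_um = f),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("<neighbor_graph> %d cells, %d Voronoi neighbor pairs\n",
              x$n, nrow(x$edges)))
  invisible(x)
}

#' Plot the clipped Voronoi tessellation
#'
#' @param x A \code{neighbor_graph}.
#' @param labels Optional per-cell factor used to colour the cells.
#' @param ... Passed to \code{plot}.
#' @export
plot.neighbor_graph <- function(x, labels = NULL, ...) {
  f <- x$frame_um
  plot(NA, xlim = c(0, f[1]), ylim = c(0, f[2]), asp = 1,
       xlab = "x (um)", ylab = "y (um)", ...)
  cols <- if (is.null(labels)) rep("grey90", x$n) else
    grDevices::hcl.colors(nlevels(factor(labels)), "Dark 3")[as.integer(factor(labels))]
  for (i in seq_len(x$n)) {
    p <- x$polygons[[i]]
    graphics::polygon(p[, 1], p[, 2], col = cols[i], border = "white")
  }
  invisible(x)
}

#' Export clipped Voronoi cells as GeoJSON
#'
#' One Polygon feature per cell with its cell id (and optional properties),
#' for plotting parity with external tools.
#'
#' @param g A \code{neighbor_graph}.
#' @param path Output path.
#' @param properties Optional data.frame of per-cell properties.
#' @export
write_voronoi_geojson <- function(g, path, properties = NULL) {
  feats <- lapply(seq_len(g$n), function(i) {
    p <- g$polygons[[i]]
    ring <- rbind(p, p[1, , drop = FALSE])
    props <- list(cell_id = g$cell_id[i])
    if (!is.null(properties)) props <- c(props, as.list(properties[i, , drop = FALSE]))
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(k) as.numeric(ring[k, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

pair_index_table <- function(K) {
  a <- rep(seq_len(K), times = K - seq_len(K) + 1)
  b <- unlist(lapply(seq_len(K), function(i) i:K))
  data.frame(a = a, b = b)
}

#' Phenotype attraction/avoidance permutation test
#'
#' For every unordered phenotype pair (same-type pairs included), counts the
#' Voronoi neighbor edges joining the two phenotypes and compares the count to
#' a Monte Carlo null in which the phenotype labels are randomly permuted over
#' the fixed cell positions (phenotype counts conserved). Z is the observed
#' count standardized by the null mean and SD; the p value is two-sided (twice
#' the smaller permutation tail, add-one corrected so p is never 0, capped at
#' 1), which keeps the rate of p < 0.01 flags at the nominal level under
#' complete spatial randomness.
#' A pair is called an attraction when Z > \code{z_thresh} and
#' p < \code{p_thresh}, an avoidance when Z < -\code{z_thresh} and
#' p < \code{p_thresh}, otherwise ns. Pairs with a degenerate null
#' (zero SD, e.g. a single phenotype) are flagged and not called.
#'
#' @param g A \code{neighbor_graph}.
#' @param labels Per-cell phenotype labels (same order as the graph's cells).
#' @param n_iter Number of label permutations (>= 100; default 1000).
#' @param seed Integer seed.
#' @param z_thresh,p_thresh Call thresholds (defaults 2 and 0.01).
#' @return An \code{interaction_result} data.frame: \code{phenotype_a},
#'   \code{phenotype_b}, \code{observed}, \code{null_mean}, \code{null_sd},
#'   \code{z}, \code{p}, \code{call}, \code{degenerate}.
#' @export
interaction_test <- function(g, labels, n_iter = 1000, seed = 1,
                             z_thresh = 2, p_thresh = 0.01) {
  stopifnot(inherits(g, "neighbor_graph"), length(labels) == g$n, n_iter >= 100)
  lev <- sort(unique(as.character(labels)))
  K <- length(lev)
  code <- match(as.character(labels), lev)
  obs_mat <- permuted_pair_counts_cpp(g$edges, code, K, 1L,
                                      matrix(seq_len(g$n), nrow = 1))
  perms <- with_seed(seed, {
    t(vapply(seq_len(n_iter), function(i) sample.int(g$n), integer(g$n)))
  })
  null_mat <- permuted_pair_counts_cpp(g$edges, code, K, n_iter, perms)
  idx <- pair_index_table(K)
  obs <- as.integer(obs_mat[1, ])
  mu <- colMeans(null_mat)
  sdv <- apply(null_mat, 2, sd)
  z <- ifelse(sdv > 0, (obs - mu) / sdv, NA_real_)
  p <- vapply(seq_along(obs), function(i) {
    if (sdv[i] == 0) return(NA_real_)
    up <- (1 + sum(null_mat[, i] >= obs[i])) / (n_iter + 1)
    dn <- (1 + sum(null_mat[, i] <= obs[i])) / (n_iter + 1)
    min(1, 2 * min(up, dn))
  }, numeric(1))
  call <- rep("ns", length(obs))
  call[!is.na(z) & z > z_thresh & p < p_thresh] <- "attraction"
  call[!is.na(z) & z < -z_thresh & p < p_thresh] <- "avoidance"
  out <- data.frame(phenotype_a = lev[idx$a], phenotype_b = lev[idx$b],
                    observed = obs, null_mean = mu, null_sd = sdv,
                    z = z, p = p, call = call, degenerate = sdv == 0,
                    stringsAsFactors = FALSE)
  structure(out, class = c("interaction_result", "data.frame"),
            n_iter = n_iter, seed = seed)
}

#' Stouffer combination of per-ROI Z scores
#'
#' Combines the Z scores of one phenotype pair across regions of interest as
#' \code{sum(z) / sqrt(k)}; non-finite entries (degenerate ROIs) are excluded
#' upstream or dropped here, and an empty list gives NA.
#'
#' @param z Numeric vector of per-ROI Z scores.
#' @return The cohort Z (scalar), or NA for an empty input.
#' @export
stouffer_combine <- function(z) {
  z <- z[is.finite(z)]
  if (!length(z)) return(NA_real_)
  sum(z) / sqrt(length(z))
}

#' PD1+/PDL1+ microaggregates
#'
#' Restricts the Voronoi neighbor graph to cells flagged as PDL1-positive
#' tumor or PD1-positive immune cells, finds connected components of the
#' restriction, and keeps the components containing at least one cell of each
#' class.
#'
#' @param g A \code{neighbor_graph}.
#' @param tumor_pdl1,immune_pd1 Per-cell logical flags.
#' @return List of \code{microaggregate}s: each a list with \code{cells}
#'   (cell ids), \code{n_pdl1_tumor}, \code{n_pd1_immune}.
#' @export
microaggregates <- function(g, tumor_pdl1, immune_pd1) {
  stopifnot(length(tumor_pdl1) == g$n, length(immune_pd1) == g$n)
  active <- which(tumor_pdl1 | immune_pd1)
  if (!length(active)) return(list())
  keep <- g$edges[, 1] %in% active & g$edges[, 2] %in% active
  gr <- igraph::graph_from_edgelist(
    matrix(as.character(g$edges[keep, , drop = FALSE]), ncol = 2),
    directed = FALSE)
  gr <- igraph::add_vertices(gr,
    length(setdiff(as.character(active), igraph::V(gr)$name)),
    name = setdiff(as.character(active), igraph::V(gr)$name))
  comp <- igraph::components(gr)
  out <- list()
  for (ci in seq_len(comp$no)) {
    members <- as.integer(igraph::V(gr)$name[comp$membership == ci])
    nt <- sum(tumor_pdl1[members])
    ni <- sum(immune_pd1[members])
    if (nt >= 1 && ni >= 1) {
      out[[length(out) + 1L]] <- structure(
        list(cells = g$cell_id[sort(members)], n_pdl1_tumor = nt, n_pd1_immune = ni),
        class = "microaggregate")
    }
  }
  out
}

#' Microaggregate permutation test
#'
#' Tests whether the number of qualifying PD1+/PDL1+ microaggregates exceeds
#' chance: both flag vectors are independently permuted over the fixed cell
#' positions (class sizes conserved) and the component count recomputed each
#' iteration; Z and the two-sided add-one p are formed as in
#' \code{\link{interaction_test}}.
#'
#' @param g A \code{neighbor_graph}.
#' @param tumor_pdl1,immune_pd1 Per-cell logical flags.
#' @param n_iter Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return List: \code{observed}, \code{null_mean}, \code{null_sd}, \code{z},
#'   \code{p}, \code{degenerate}.
#' @export
microaggregate_test <- function(g, tumor_pdl1, immune_pd1, n_iter = 1000, seed = 1) {
  stopifnot(inherits(g, "neighbor_graph"), n_iter >= 100)
  id <- matrix(seq_len(g$n), nrow = 1)
  obs <- microagg_counts_cpp(g$edges, tumor_pdl1, immune_pd1, id, id)[1]
  perms <- with_seed(seed, {
    list(t(vapply(seq_len(n_iter), function(i) sample.int(g$n), integer(g$n))),
         t(vapply(seq_len(n_iter), function(i) sample.int(g$n), integer(g$n))))
  })
  null <- microagg_counts_cpp(g$edges, tumor_pdl1, immune_pd1,
                              perms[[1]], perms[[2]])
  mu <- mean(null); sdv <- sd(null)
  if (sdv == 0) {
    return(list(observed = obs, null_mean = mu, null_sd = 0, z = NA_real_,
                p = NA_real_, degenerate = TRUE))
  }
  z <- (obs - mu) / sdv
  up <- (1 + sum(null >= obs)) / (n_iter + 1)
  dn <- (1 + sum(null <= obs)) / (n_iter + 1)
  p <- min(1, 2 * min(up, dn))
  list(observed = obs, null_mean = mu, null_sd = sdv, z = z, p = p,
       degenerate = FALSE)
}

#' Read / write a cell table CSV
#'
#' Columns: \code{cell_id}, \code{roi_id}, \code{x_um}, \code{y_um},
#' \code{phenotype}, one column per marker positive-area fraction.
#'
#' @param path CSV path.
#' @param frame_um ROI frame (width, height) in micrometres.
#' @return A \code{cell_map}.
#' @export
read_cell_map <- function(path, frame_um) {
  as_cell_map(utils::read.csv(path, stringsAsFactors = FALSE), frame_um)
}

#' @rdname read_cell_map
#' @param c A \code{cell_map} to write.
#' @export
write_cell_map <- function(c, path) {
  write.csv(as.data.frame(c), path, row.names = FALSE)
  invisible(path)
}
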