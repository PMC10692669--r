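#' Generate a synthetic prior causal signaling network
#'
#' Builds a weakly connected, directed, signed kinase/substrate network in the
#' style of a curated causal signaling resource: every edge originates at a
#' kinase, carries an activation/inhibition sign, a mechanism label, and one or
#' more annotated phosphosite residues on the target protein (e.g.
#' \code{"S473"}). Residue positions are unique per target protein so that
#' every annotated site maps to exactly one edge.
#'
#' Weak connectivity is guaranteed by first drawing a random spanning
#' arborescence whose parents are kinases, then adding random kinase-sourced
#' edges until the requested density is reached. If the density implies fewer
#' edges than \code{n_kinases + n_substrates - 1}, connectivity is impossible
#' and an error reports the minimum feasible density.
#'
#' @param n_kinases Number of kinase nodes (>= 2); these are the only nodes
#'   with outgoing edges.
#' @param n_substrates Number of substrate-only nodes.
#' @param edge_density Fraction of the possible kinase-sourced ordered pairs to
#'   realise as edges, in (0, 1].
#' @param seed Integer seed; identical arguments and seed give an identical
#'   edge list.
#' @return An object of class \code{prior_network}: an \pkg{igraph} directed
#'   graph with vertex attributes \code{name}, \code{kind} and edge attributes
#'   \code{sign} (+1/-1), \code{mechanism}, \code{residues}
#'   (comma-separated site annotations on the target).
#' @examples
#' net <- gen_prior_network(5, 10, 0.2, seed = 1)
#' igraph::ecount(net)
#' @export
gen_prior_network <- function(n_kinases, n_substrates = 0, edge_density = 0.1,
                              seed = 1) {
  if (n_kinases < 2) stopf("n_kinases must be >= 2, got %d", n_kinases)
  if (edge_density <= 0 || edge_density > 1) {
    stopf("edge_density must be in (0, 1], got %g", edge_density)
  }
  n <- n_kinases + n_substrates
  kin <- sprintf("KIN%02d", seq_len(n_kinases))
  sub <- if (n_substrates > 0) sprintf("SUB%02d", seq_len(n_substrates)) else character()
  nodes <- c(kin, sub)
  # possible ordered edges: kinase -> any other node
  possible <- n_kinases * (n - 1)
  n_edges <- round(edge_density * possible)
  if (n_edges < n - 1) {
    stopf(paste0(
      "edge_density %g gives %d edges but weak connectivity needs at least ",
      "%d; minimum feasible density is %g"
    ), edge_density, n_edges, n - 1, (n - 1) / possible)
  }
  with_seed(seed, {
    from <- character(n - 1)
    to <- character(n - 1)
    # spanning structure: every node after the first gets a kinase parent
    for (i in seq_len(n - 1)) {
      child <- nodes[i + 1]
      avail <- kin[seq_len(min(i, n_kinases))]
      from[i] <- if (length(avail) == 1) avail else sample(avail, 1)
      to[i] <- child
    }
    have <- paste(from, to)
    extra <- n_edges - (n - 1)
    if (extra > 0) {
      all_from <- rep(kin, each = n - 1)
      all_to <- unlist(lapply(kin, function(k) setdiff(nodes, k)), use.names = FALSE)
      key <- paste(all_from, all_to)
      free <- which(!(key %in% have))
      pick <- if (length(free) == 1) free else sample(free, extra)
      from <- c(from, all_from[pick])
      to <- c(to, all_to[pick])
    }
    sign <- sample(c(1L, -1L), length(from), replace = TRUE, prob = c(0.75, 0.25))
    mech <- ifelse(sign > 0, "phosphorylation", "dephosphorylation")
    # residue annotations, unique positions within each target protein
    used <- new.env(parent = emptyenv())
    residues <- vapply(seq_along(to), function(i) {
      tgt <- to[i]
      k <- 1L + rbinom(1L, 2L, 0.2)
      prev <- if (is.null(used[[tgt]])) integer() else used[[tgt]]
      pos <- sample(setdiff(5:400, prev), k)
      used[[tgt]] <- c(prev, pos)
      letters_ <- sample(c("S", "T", "Y"), k, replace = TRUE, prob = c(0.6, 0.3, 0.1))
      paste0(letters_, pos, collapse = ",")
    }, character(1))
    g <- igraph::graph_from_data_frame(
      data.frame(from = from, to = to, sign = sign, mechanism = mech,
                 residues = residues, stringsAsFactors = FALSE),
      directed = TRUE,
      vertices = data.frame(name = nodes,
                            kind = c(rep("kinase", n_kinases),
                                     rep("substrate", n_substrates)),
                            stringsAsFactors = FALSE)
    )
    class(g) <- c("prior_network", class(g))
    g
  })
}

#' Derive a directional signature database from a prior network
#'
#' One signature per kinase, listing the phosphosites annotated on its
#' outgoing edges. Sites on activating edges are flagged up (\code{"u"}), sites
#' on inhibiting edges down (\code{"d"}), mirroring how kinase signatures in
#' site-centric PTM signature databases encode the expected direction of
#' regulation when the kinase is active.
#'
#' @param net A \code{prior_network}.
#' @param category Signature category label (default \code{"KINASE"}).
#' @return A \code{signature_db}: data.frame with columns \code{signature},
#'   \code{category}, \code{site} (\code{"ACC;S473"}) and \code{direction}.
#' @export
gen_signature_db <- function(net, category = "KINASE") {
  ed <- igraph::as_data_frame(net, what = "edges")
  rows <- lapply(seq_len(nrow(ed)), function(i) {
    res <- strsplit(ed$residues[i], ",", fixed = TRUE)[[1]]
    data.frame(signature = ed$from[i], category = category,
               site = paste0(ed$to[i], ";", res),
               direction = if (ed$sign[i] > 0) "u" else "d",
               stringsAsFactors = FALSE)
  })
  db <- do.call(rbind, rows)
  db <- db[!duplicated(db[c("signature", "site")]), , drop = FALSE]
  db <- db[order(db$signature, db$site), , drop = FALSE]
  rownames(db) <- NULL
  class(db) <- c("signature_db", "data.frame")
  db
}

# Planted downstream effects of inhibiting `target`: every edge (u, v) with
# dist(target, u) <= 1 contributes its sites, shifted by -effect * path sign.
planted_effects <- function(net, target, effect_log2) {
  ed <- igraph::as_data_frame(net, what = "edges")
  d <- igraph::distances(net, v = target, mode = "out")[1, ]
  out <- list()
  for (i in seq_len(nrow(ed))) {
    u <- ed$from[i]
    if (!is.finite(d[u]) || d[u] > 1) next
    path_sign <- if (u == target) {
      ed$sign[i]
    } else {
      first <- ed$sign[ed$from == target & ed$to == u][1]
      first * ed$sign[i]
    }
    res <- strsplit(ed$residues[i], ",", fixed = TRUE)[[1]]
    out[[length(out) + 1L]] <- data.frame(
      protein = ed$to[i],
      residue = sub("[0-9]+$", "", res),
      position = as.integer(sub("^[A-Z]", "", res)),
      shift = -path_sign * effect_log2,
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(protein = character(), residue = character(),
                      position = integer(), shift = numeric()))
  }
  eff <- do.call(rbind, out)
  # a site reached by several paths keeps the first (shortest-path-ordered) shift
  eff[!duplicated(eff[c("protein", "residue", "position")]), , drop = FALSE]
}

#' Generate a synthetic inhibitor-perturbation phosphoproteomic dataset
#'
#' Emulates fragment-level DIA phosphoproteomics of organoids treated with
#' single kinase inhibitors. Every annotated phosphosite in the prior network
#' yields one phosphopeptide with \code{n_fragments} fragments. Log2
#' intensities are log-normal around per-fragment baselines
#' (N(12, 1) on the log2 scale, so an absolute intensity filter at 2000 removes
#' a realistic low tail), with per-sample loading offsets and per-peptide
#' biological wobble that make fragments of one peptide coherent across
#' samples. Sites on edges within two hops downstream of each inhibited target
#' are shifted by \code{effect_log2} with sign opposite to the net edge effect,
#' as expected under kinase inhibition. Fragments of planted peptides draw
#' their baselines from the upper tail (>= 11.5 log2) so the perturbed sites
#' remain quantifiable in the control arm, emulating well-measured inhibitor
#' targets.
#'
#' @param net A \code{prior_network}.
#' @param targets Character vector of kinase nodes, one treatment per target.
#' @param effect_log2 Planted log2 effect size (paper-scale perturbations use
#'   around 3). Zero with non-empty targets warns (null planted).
#' @param n_reps Replicates per condition (>= 2).
#' @param noise_sd Replicate-level technical noise, log2 scale.
#' @param seed Integer seed.
#' @param n_fragments Fragments per peptide (>= 5 so peptides can survive the
#'   minimum-fragment filter).
#' @param dropout_rate Probability that an individual fragment measurement is
#'   missing, emulating DIA dropouts.
#' @return A list with components \code{fragments} (a \code{fragment_table}),
#'   \code{proteome} (named character vector of protein sequences) and
#'   \code{truth} (a \code{ground_truth} list: per-treatment target kinase,
#'   planted differential sites with expected sign, and the seed).
#' @export
gen_perturbation_dataset <- function(net, targets, effect_log2 = 3, n_reps = 3,
                                     noise_sd = 0.1, seed = 1, n_fragments = 8,
                                     dropout_rate = 0.05) {
  stopifnot(all(targets %in% igraph::V(net)$name))
  if (n_reps < 2) stopf("n_reps must be >= 2, got %d", n_reps)
  if (effect_log2 == 0 && length(targets) > 0) {
    warnf("effect_log2 = 0 with a non-empty target list: planted effects are null")
  }
  ed <- igraph::as_data_frame(net, what = "edges")
  # site catalogue: one row per annotated residue
  site_rows <- do.call(rbind, lapply(seq_len(nrow(ed)), function(i) {
    res <- strsplit(ed$residues[i], ",", fixed = TRUE)[[1]]
    data.frame(protein = ed$to[i],
               residue = sub("[0-9]+$", "", res),
               position = as.integer(sub("^[A-Z]", "", res)),
               stringsAsFactors = FALSE)
  }))
  site_rows <- site_rows[!duplicated(site_rows), , drop = FALSE]
  site_rows <- site_rows[order(site_rows$protein, site_rows$position), , drop = FALSE]

  treatments <- paste0("TRT_", targets)
  conditions <- c("CTRL", treatments)
  effects <- lapply(targets, planted_effects, net = net, effect_log2 = effect_log2)
  names(effects) <- treatments

  with_seed(seed, {
    # protein sequences consistent with the annotated residues
    prots <- unique(site_rows$protein)
    aa <- strsplit("ACDEFGHIKLMNPQRVW", "")[[1]]
    proteome <- vapply(prots, function(p) {
      rows <- site_rows[site_rows$protein == p, ]
      len <- max(30L, max(rows$position) + 10L)
      s <- sample(aa, len, replace = TRUE)
      s[rows$position] <- rows$residue
      paste(s, collapse = "")
    }, character(1))

    planted_key <- unique(unlist(lapply(effects, function(e) {
      paste(e$protein, e$residue, e$position)
    })))

    # one peptide per site: a sequence window around the phosphosite
    peps <- lapply(seq_len(nrow(site_rows)), function(i) {
      p <- site_rows$protein[i]; pos <- site_rows$position[i]
      seqp <- proteome[[p]]
      start <- max(1L, pos - 4L)
      end <- min(nchar(seqp), pos + 5L)
      data.frame(peptide_id = sprintf("pep%03d", i), protein = p,
                 sequence = substr(seqp, start, end),
                 offsets = pos - start + 1L,
                 residue = site_rows$residue[i], position = pos,
                 stringsAsFactors = FALSE)
    })
    peptides <- do.call(rbind, peps)

    samples <- expand.grid(replicate = seq_len(n_reps), condition = conditions,
                           stringsAsFactors = FALSE)
    samples$sample <- paste0(samples$condition, "_R", samples$replicate)
    loading <- rnorm(nrow(samples), 0, 0.3)

    rows <- vector("list", nrow(peptides))
    for (i in seq_len(nrow(peptides))) {
      key <- paste(peptides$protein[i], peptides$residue[i], peptides$position[i])
      base <- rnorm(n_fragments, 12, 1)
      if (key %in% planted_key) {
        low <- base < 11.5
        while (any(low)) {
          base[low] <- rnorm(sum(low), 12, 1)
          low <- base < 11.5
        }
      }
      shift <- vapply(samples$condition, function(cond) {
        if (cond == "CTRL") return(0)
        e <- effects[[cond]]
        hit <- e$protein == peptides$protein[i] & e$position == peptides$position[i]
        if (any(hit)) e$shift[hit][1] else 0
      }, numeric(1))
      wobble <- rnorm(nrow(samples), 0, 0.15)
      lv <- outer(base, loading + wobble + shift, "+") +
        rnorm(n_fragments * nrow(samples), 0, noise_sd)
      inten <- 2^lv
      inten[runif(length(inten)) < dropout_rate] <- NA_real_
      rows[[i]] <- data.frame(
        peptide_id = peptides$peptide_id[i],
        fragment_id = paste0(peptides$peptide_id[i], "_f", rep(seq_len(n_fragments), nrow(samples))),
        sample = rep(samples$sample, each = n_fragments),
        condition = rep(samples$condition, each = n_fragments),
        replicate = rep(samples$replicate, each = n_fragments),
        intensity = as.vector(inten),
        stringsAsFactors = FALSE
      )
    }
    frag <- fragment_table(do.call(rbind, rows),
                           peptides[c("peptide_id", "protein", "sequence", "offsets")],
                           control = "CTRL")
    planted <- do.call(rbind, lapply(treatments, function(tr) {
      e <- effects[[tr]]
      if (!nrow(e)) return(NULL)
      data.frame(treatment = tr, protein = e$protein, residue = e$residue,
                 position = e$position, expected_sign = sign(e$shift),
                 stringsAsFactors = FALSE)
    }))
    truth <- structure(list(
      target_kinases = stats::setNames(as.list(targets), treatments),
      planted_differential_sites = planted,
      rng_seed = seed
    ), class = "ground_truth")
    list(fragments = frag, proteome = proteome, truth = truth)
  })
}

#' Generate a synthetic spatial cell map
#'
#' Emulates a post-segmentation imaging-mass-cytometry cell table for one
#' region of interest: cell centroids in micrometres, a phenotype label per
#' cell, and optional per-marker positive-area fractions. Non-interacting
#' phenotypes are placed uniformly (complete spatial randomness). Each
#' attraction pair is realised as a bivariate Thomas cluster process with
#' shared parents: a small set of parent locations is drawn uniformly, and
#' cells of both paired phenotypes are placed, with probability
#' \code{strength / (1 + strength)} each, at a Gaussian displacement
#' (sd \code{sigma_um}) from a random shared parent — co-clustering around
#' common niches is what makes the two phenotypes mutual Voronoi neighbors
#' far above chance. \code{strength = 0} reduces exactly to complete spatial
#' randomness. A self-pair \code{c("a", "a")} gives the univariate Thomas
#' process (within-phenotype clustering).
#'
#' @param n_cells Total number of cells (>= 3; a Voronoi tessellation is
#'   undefined below that).
#' @param phenotype_props Named numeric vector of phenotype proportions,
#'   summing to 1.
#' @param attract_pairs List of length-2 character vectors of phenotype names;
#'   a phenotype may take part in at most one pair.
#' @param strength Non-negative attraction strength; 0 means none.
#' @param frame_um ROI frame c(width, height) in micrometres.
#' @param seed Integer seed.
#' @param markers Optional named list: phenotype -> named vector of mean
#'   positive-area fractions; unlisted phenotype/marker combinations default to
#'   a low background mean of 0.02. Fractions are drawn from Beta
#'   distributions with the given means.
#' @param sigma_um Cluster spread (Gaussian sd of the displacement from the
#'   parent) in micrometres; the default 15 gives niches a couple of cell diameters
#'   across.
#' @param parents_per_mm2 Intensity of the shared Thomas parents (default 6
#'   parents per square millimetre, at least 2 per ROI).
#' @param roi_id ROI identifier stored with each cell.
#' @return A list with \code{cells} (a \code{cell_map} data.frame: cell_id,
#'   roi_id, x_um, y_um, phenotype, one column per marker; frame stored as an
#'   attribute) and \code{truth} (planted attraction pairs, strength, seed).
#' @export
gen_cell_map <- function(n_cells, phenotype_props, attract_pairs = list(),
                         strength = 0, frame_um = c(1000, 1000), seed = 1,
                         markers = NULL, sigma_um = 15, parents_per_mm2 = 6,
                         roi_id = "ROI1") {
  if (n_cells < 3) stopf("n_cells must be >= 3 (Voronoi undefined), got %d", n_cells)
  if (abs(sum(phenotype_props) - 1) > 1e-8) {
    stopf("phenotype proportions must sum to 1 (got %g)", sum(phenotype_props))
  }
  if (strength < 0) stopf("strength must be >= 0")
  in_pairs <- unlist(attract_pairs)
  if (anyDuplicated(unlist(lapply(attract_pairs, unique)))) {
    stopf("a phenotype may take part in at most one attraction pair")
  }
  phenos <- names(phenotype_props)
  counts <- floor(phenotype_props * n_cells)
  rem <- n_cells - sum(counts)
  if (rem > 0) counts[order(phenotype_props * n_cells - counts, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(phenotype_props * n_cells - counts, decreasing = TRUE)[seq_len(rem)]] + 1
  with_seed(seed, {
    placed <- list()
    p_cluster <- strength / (1 + strength)
    reflect <- function(v, lim) {
      v <- abs(v)
      v <- lim - abs(lim - v %% (2 * lim))
      v
    }
    # shared Thomas parents, one parent set per attraction pair
    n_parents <- max(2L, round(parents_per_mm2 * prod(frame_um) / 1e6))
    parent_of <- list()   # phenotype -> parent coordinate matrix
    for (pr in attract_pairs) {
      px <- runif(n_parents, 0, frame_um[1])
      py <- runif(n_parents, 0, frame_um[2])
      for (ph in unique(pr)) parent_of[[ph]] <- cbind(px, py)
    }
    for (ph in phenos) {
      k <- counts[[ph]]
      if (k == 0) next
      x <- runif(k, 0, frame_um[1]); y <- runif(k, 0, frame_um[2])
      if (!is.null(parent_of[[ph]]) && strength > 0) {
        centres <- parent_of[[ph]]
        cl <- runif(k) < p_cluster
        if (any(cl)) {
          nc <- sum(cl)
          j <- sample.int(nrow(centres), nc, replace = TRUE)
          x[cl] <- reflect(centres[j, 1] + rnorm(nc, 0, sigma_um), frame_um[1])
          y[cl] <- reflect(centres[j, 2] + rnorm(nc, 0, sigma_um), frame_um[2])
        }
      }
      placed[[ph]] <- data.frame(x = x, y = y, phenotype = ph,
                                 stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, placed[phenos[phenos %in% names(placed)]])
    df <- df[sample.int(nrow(df)), , drop = FALSE]  # shuffle so ids are not grouped
    cells <- data.frame(cell_id = sprintf("c%04d", seq_len(nrow(df))),
                        roi_id = roi_id, x_um = df$x, y_um = df$y,
                        phenotype = df$phenotype, stringsAsFactors = FALSE)
    if (!is.null(markers)) {
      marker_names <- unique(unlist(lapply(markers, names)))
      for (m in marker_names) {
        mu <- vapply(cells$phenotype, function(ph) {
          v <- markers[[ph]][m]
          if (is.null(v) || is.na(v)) 0.02 else as.numeric(v)
        }, numeric(1))
        cells[[m]] <- rbeta(nrow(cells), mu * 10, (1 - mu) * 10)
      }
    }
    rownames(cells) <- NULL
    cells <- as_cell_map(cells, frame_um = frame_um)
    truth <- structure(list(
      planted_attractions = attract_pairs,
      strength = strength,
      rng_seed = seed
    ), class = "ground_truth")
    list(cells = cells, truth = truth)
  })
}

#' Generate per-sample coding-mutation gene lists
#'
#' Each network node is mutated independently with probability \code{rate} in
#' each sample, emulating per-sample coding-variant gene lists.
#'
#' @param net A \code{prior_network}.
#' @param rate Per-gene mutation probability.
#' @param seed Integer seed.
#' @param sample_ids Character vector of sample identifiers.
#' @return data.frame with columns \code{sample}, \code{gene}.
#' @export
gen_mutations <- function(net, rate, seed = 1, sample_ids = "S1") {
  stopifnot(rate >= 0, rate <= 1)
  nodes <- igraph::V(net)$name
  with_seed(seed, {
    out <- do.call(rbind, lapply(sample_ids, function(s) {
      hit <- nodes[runif(length(nodes)) < rate]
      if (!length(hit)) return(NULL)
      data.frame(sample = s, gene = hit, stringsAsFactors = FALSE)
    }))
    if (is.null(out)) out <- data.frame(sample = character(), gene = character())
    out
  })
}

#' Generate correlated protein-complex abundance matrices
#'
#' Subunits of the same complex share a latent per-sample factor so that every
#' within-complex pair has Pearson correlation \code{rho} (equicorrelation);
#' proteins outside the catalog, or the residual part of each subunit, are
#' independent noise. Abundances are on the log2 scale.
#'
#' @param catalog data.frame with columns \code{complex_id}, \code{member}
#'   (a \code{complex_catalog}); a member listed in several complexes is driven
#'   by its first complex.
#' @param rho Within-complex correlation in [0, 1).
#' @param n_samples Number of samples.
#' @param seed Integer seed.
#' @return Numeric matrix (members x samples) of log2 abundances.
#' @export
gen_complex_abundance <- function(catalog, rho, n_samples, seed = 1) {
  stopifnot(rho >= 0, rho < 1)
  members <- catalog$member[!duplicated(catalog$member)]
  first_complex <- catalog$complex_id[match(members, catalog$member)]
  with_seed(seed, {
    cx <- unique(first_complex)
    factors <- matrix(rnorm(length(cx) * n_samples), length(cx),
                      dimnames = list(cx, NULL))
    mu <- rnorm(length(members), 25, 2)
    eps <- matrix(rnorm(length(members) * n_samples), length(members))
    m <- mu + sqrt(rho) * factors[first_complex, , drop = FALSE] +
      sqrt(1 - rho) * eps
    dimnames(m) <- list(members, sprintf("S%02d", seq_len(n_samples)))
    m
  })
}
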