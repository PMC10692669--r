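#' Default pipeline configuration
#'
#' Every analysis default equals the corresponding published setting where one
#' exists: FDR gates 0.05, fold-change cut |log2FC| > 1, fragment intensity
#' filter 2000 with >= 5 fragments and >= 2 detections per condition, SD
#' factor 2 and minimum fragment correlation 0.25, marker positivity 10%,
#' 1000 spatial permutation iterations with |Z| > 2 and p < 0.01 calls.
#' Simulation block parameters define the bundled synthetic demo inputs.
#'
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return A named list (class \code{run_config}).
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = as.integer(seed),
    thresholds = list(
      node_fdr = 0.05, edge_fdr = 0.05, log2fc_cut = 1,
      min_intensity = 2000, min_fragments = 5, min_detected_per_condition = 2,
      sd_factor = 2, min_corr = 0.25, fdr_floor = 1e-10,
      positivity = 0.10, z_thresh = 2, p_thresh = 0.01, min_overlap = 2
    ),
    n_perm = list(enrichment = 1000, spatial = 1000),
    simulate = list(
      n_kinases = 8, n_substrates = 14, edge_density = 0.2,
      targets = c("KIN01", "KIN02"), effect_log2 = 3, n_reps = 3,
      noise_sd = 0.1, mutation_rate = 0.1,
      n_cells = 400, phenotype_props = c(tumor = 0.4, immune = 0.3, stroma = 0.3),
      attract_pairs = list(c("tumor", "immune")), strength = 3,
      frame_um = c(1000, 1000),
      n_complexes = 8, complex_size = 6, rho = 0.6, n_samples = 12
    )
  ), class = "run_config")
}

#' Validate a pipeline configuration
#'
#' Checks every threshold against its valid range and the presence of a seed;
#' the first violated field is named in the error.
#'
#' @param config A \code{run_config} list.
#' @return The config, invisibly, if valid.
#' @export
validate_config <- function(config) {
  th <- config$thresholds
  check <- function(name, lo, hi) {
    v <- th[[name]]
    if (is.null(v) || !is.numeric(v) || v < lo || v > hi) {
      stopf("config field 'thresholds.%s' out of range [%g, %g]: %s",
            name, lo, hi, if (is.null(v)) "missing" else format(v))
    }
  }
  for (f in c("node_fdr", "edge_fdr")) check(f, 0, 1)
  check("p_thresh", 0, 1)
  check("positivity", 0, 1)
  check("min_corr", -1, 1)
  for (f in c("log2fc_cut", "min_intensity", "min_fragments",
              "min_detected_per_condition", "sd_factor", "z_thresh")) {
    check(f, 0, Inf)
  }
  if (is.null(config$seed)) stopf("config field 'seed' is mandatory")
  for (f in names(config$n_perm)) {
    if (config$n_perm[[f]] < 100) stopf("config field 'n_perm.%s' must be >= 100", f)
  }
  invisible(config)
}

#' Read / write a configuration as YAML
#' @param path YAML path.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$simulate$phenotype_props <- unlist(cfg$simulate$phenotype_props)
  cfg$simulate$frame_um <- as.numeric(unlist(cfg$simulate$frame_um))
  structure(cfg, class = "run_config")
}

#' @rdname read_config
#' @param config A \code{run_config}.
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  # yaml serialises named atomic vectors as plain sequences; store the
  # phenotype proportions as a map so the names survive the round trip
  cfg$simulate$phenotype_props <- as.list(cfg$simulate$phenotype_props)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Run the full pipeline from a configuration
#'
#' Executes the stages in dependency order — simulate (synthetic inputs with
#' ground-truth sidecar), phospho (filter/impute/map/differential), enrich
#' (site-centric signed enrichment), network (annotate/extract/prune/merge,
#' centralities, mutation test), spatial (Voronoi neighborhoods, interaction
#' and microaggregate permutation tests) and complexes (co-abundance) — and
#' writes every artifact plus a manifest with md5 hashes, parameter values and
#' per-stage seeds. Reruns with an identical configuration reproduce every
#' output file bit-identically.
#'
#' @param config A \code{run_config} (see \code{\link{default_config}}) or a
#'   path to a YAML config.
#' @param outdir Output directory (created if absent).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = default_config(), outdir = tempfile("phosnet_run_")) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  th <- config$thresholds
  seed <- config$seed
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ip <- function(...) file.path(outdir, ...)
  artifacts <- character()
  log_lines <- character()
  say <- function(...) {
    msg <- sprintf(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }

  ## stage: simulate -----------------------------------------------------
  sim <- config$simulate
  say("stage simulate: generating synthetic inputs (seed %d)", seed)
  net <- gen_prior_network(sim$n_kinases, sim$n_substrates, sim$edge_density,
                           seed = derive_seed(seed, 1))
  db <- gen_signature_db(net)
  pert <- gen_perturbation_dataset(net, sim$targets, sim$effect_log2,
                                   sim$n_reps, sim$noise_sd,
                                   seed = derive_seed(seed, 2))
  muts <- gen_mutations(net, sim$mutation_rate, seed = derive_seed(seed, 3))
  cmap <- gen_cell_map(sim$n_cells, sim$phenotype_props, sim$attract_pairs,
                       sim$strength, sim$frame_um, seed = derive_seed(seed, 4),
                       markers = list(tumor = c(PDL1 = 0.3), immune = c(PD1 = 0.3)))
  catalog <- data.frame(
    complex_id = rep(sprintf("CPX%02d", seq_len(sim$n_complexes)),
                     each = sim$complex_size),
    member = sprintf("PRT%03d", seq_len(sim$n_complexes * sim$complex_size)),
    stringsAsFactors = FALSE)
  abund <- gen_complex_abundance(catalog, sim$rho, sim$n_samples,
                                 seed = derive_seed(seed, 5))
  write_signor(net, ip("prior_network.tsv"))
  write_gmt(db, ip("signatures.gmt"))
  write_fragments(pert$fragments, ip("fragments.csv"), ip("peptides.csv"))
  write_fasta(pert$proteome, ip("proteome.fasta"))
  write_ground_truth(pert$truth, ip("ground_truth.json"))
  utils::write.table(muts, ip("mutations.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  write_cell_map(cmap$cells, ip("cell_map.csv"))
  write.csv(data.frame(member = rownames(abund), abund, check.names = FALSE),
            ip("abundance.csv"), row.names = FALSE)
  artifacts <- c(artifacts, "prior_network.tsv", "signatures.gmt", "fragments.csv",
                 "peptides.csv", "proteome.fasta", "ground_truth.json",
                 "mutations.tsv", "cell_map.csv", "abundance.csv")

  ## stage: phospho ------------------------------------------------------
  say("stage phospho: filtering, imputing and testing phosphosites")
  filt <- filter_fragments(pert$fragments, th$min_intensity, th$min_fragments,
                           th$min_detected_per_condition, th$sd_factor, th$min_corr)
  imp <- impute_missing(filt)
  sites <- map_sites(imp, pert$proteome)
  treatments <- setdiff(unique(imp$data$condition), imp$control)
  diffs <- lapply(treatments, function(tr) {
    collapse_duplicate_sites(differential(imp, sites, tr))
  })
  names(diffs) <- treatments
  diff_all <- do.call(rbind, diffs)
  write.csv(diff_all, ip("diff_sites.csv"), row.names = FALSE)
  artifacts <- c(artifacts, "diff_sites.csv")

  ## stage: enrich -------------------------------------------------------
  say("stage enrich: site-centric signed enrichment (%d permutations)",
      config$n_perm$enrichment)
  enrichments <- lapply(treatments, function(tr) {
    sc <- demultiplex(score_sites(diffs[[tr]], th$fdr_floor))
    enrich(sc, db, n_perm = config$n_perm$enrichment,
           min_overlap = th$min_overlap, seed = derive_seed(seed, 10))
  })
  names(enrichments) <- treatments
  enr_all <- do.call(rbind, lapply(treatments, function(tr) {
    cbind(treatment = tr, as.data.frame(enrichments[[tr]]))
  }))
  write.csv(enr_all, ip("enrichment.csv"), row.names = FALSE)
  artifacts <- c(artifacts, "enrichment.csv")

  ## stage: network ------------------------------------------------------
  say("stage network: subnetwork extraction and merging")
  subs <- lapply(treatments, function(tr) {
    a <- annotate_network(net, enrichments[[tr]], diffs[[tr]], treatment = tr)
    s <- tryCatch(extract_subnetwork(a, th$node_fdr, th$edge_fdr),
                  warning = function(w) {
                    say("  %s: %s", tr, conditionMessage(w))
                    suppressWarnings(extract_subnetwork(a, th$node_fdr, th$edge_fdr))
                  })
    prune_redundant_paths(s)
  })
  names(subs) <- treatments
  nonempty <- subs[vapply(subs, function(s) igraph::vcount(s$graph) > 0, logical(1))]
  merged <- if (length(nonempty)) merge_subnetworks(nonempty) else NULL
  if (!is.null(merged) && igraph::vcount(merged$graph) > 0) {
    cent <- centralities(merged)
    write.csv(cent, ip("centralities.csv"), row.names = FALSE)
    write_subnetwork(merged, ip("merged_subnetwork.graphml"),
                     ip("merged_subnetwork_edges.csv"))
    artifacts <- c(artifacts, "centralities.csv",
                   "merged_subnetwork.graphml", "merged_subnetwork_edges.csv")
    if (igraph::vcount(merged$graph) < igraph::vcount(net)) {
      fr <- mutation_enrichment(merged, net, unique(muts$gene))
      jsonlite::write_json(list(table = fr$table, odds_ratio = fr$odds_ratio, p = fr$p),
                           ip("mutation_enrichment.json"), auto_unbox = TRUE, digits = NA)
      artifacts <- c(artifacts, "mutation_enrichment.json")
    } else {
      say("  merged subnetwork spans the whole prior; mutation test skipped (no background)")
    }
  }

  ## stage: spatial ------------------------------------------------------
  say("stage spatial: Voronoi neighborhoods and permutation tests (%d iterations)",
      config$n_perm$spatial)
  g <- voronoi_neighbors(cmap$cells)
  ia <- interaction_test(g, cmap$cells$phenotype, n_iter = config$n_perm$spatial,
                         seed = derive_seed(seed, 20),
                         z_thresh = th$z_thresh, p_thresh = th$p_thresh)
  write.csv(as.data.frame(ia), ip("interactions.csv"), row.names = FALSE)
  dens <- densities(cmap$cells)
  write.csv(data.frame(phenotype = names(dens), cells_per_mm2 = as.numeric(dens)),
            ip("densities.csv"), row.names = FALSE)
  ma <- microaggregate_test(
    g,
    marker_positive(cmap$cells, "PDL1", th$positivity) & cmap$cells$phenotype == "tumor",
    marker_positive(cmap$cells, "PD1", th$positivity) & cmap$cells$phenotype == "immune",
    n_iter = config$n_perm$spatial, seed = derive_seed(seed, 21))
  jsonlite::write_json(ma, ip("microaggregates.json"), auto_unbox = TRUE, digits = NA)
  artifacts <- c(artifacts, "interactions.csv", "densities.csv", "microaggregates.json")

  ## stage: complexes ----------------------------------------------------
  say("stage complexes: co-abundance ranking")
  stab <- complex_coabundance(abund, catalog, min_members = 5)
  write.csv(stab, ip("complex_stability.csv"), row.names = FALSE)
  artifacts <- c(artifacts, "complex_stability.csv")

  ## manifest ------------------------------------------------------------
  hashes <- tools::md5sum(file.path(outdir, artifacts))
  manifest <- list(
    seed = seed,
    parameters = th,
    n_perm = config$n_perm,
    artifacts = lapply(seq_along(artifacts), function(i) {
      list(file = artifacts[i], md5 = unname(hashes[i]))
    }),
    log = log_lines
  )
  jsonlite::write_json(manifest, ip("manifest.json"), auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, ip("run.log"))
  invisible(manifest)
}
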