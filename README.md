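# phosnet

Patient-level kinase signaling-network reconstruction from perturbation
phosphoproteomics, and spatial heterocellular-interaction statistics for
imaging mass cytometry (IMC) — as one tested, reusable R package.

**Who it is for.** Groups running kinase-inhibitor perturbation screens on
patient-derived organoids (or any replicated DIA phosphoproteomics design)
who want per-treatment kinase activities and a connected signaling module
per sample; and groups with segmented IMC cell tables who want
attraction/avoidance calls between cell phenotypes, cohort meta-Z scores,
and PD1+/PDL1+ microaggregate statistics. A synthetic-data suite with
ground-truth sidecars makes every stage testable without any external
download.

## The models at the core

**Phosphosite statistics.** Fragment intensities are filtered (intensity
> 2000, ≥ 5 fragments/peptide, ≥ 2 detections in some condition, fragment
coherence by correlation ≥ 0.25 and a 2-SD rule), missing replicates are
imputed as 20% of the fragment's minimum, peptides are mapped to 1-based
protein phosphosite coordinates, and each site is tested per treatment:
log2FC = mean log2 summed-fragment signal (treatment − control), Welch
t-test, Benjamini–Hochberg FDR.

**Kinase activity.** Site-centric signed enrichment over directional
signature sets. Sites are ranked by the signed score
`sign(log2FC) · (−log10 FDR)`; a signature's running sum adds
`d_j |s_j|^w / Σ|s|^w` at member sites (direction d = ±1) and subtracts a
balancing decrement elsewhere, and the enrichment score is the area under
that running statistic. NES and p come from site-label permutations, FDR
by BH per category.

**Subnetwork extraction.** On a SIGNOR-style causal prior, perturbed
nodes (kinase-signature FDR ≤ 0.05) are connected by all directed
shortest paths of ≤ 2 hops, combined with perturbed edges (phosphosite
FDR ≤ 0.05); the largest connected component is the treatment subnetwork,
pruned of shortest paths that lack phosphosite annotation when an
annotated alternative exists. Treatment subnetworks merge into per-sample
networks with degree/eigenvector centralities and a two-sided Fisher test
for mutation overrepresentation.

**Spatial statistics.** Voronoi tessellation clipped to the ROI frame
defines cell–cell contact (shared boundary of positive length). Per
phenotype pair, the contact count is compared to a label-permutation
null: Z = (obs − mean)/SD, two-sided permutation p, calls at |Z| > 2 and
p < 0.01; per-ROI Z's combine across a cohort as Stouffer's ΣZ/√k.
PD1+/PDL1+ microaggregates are connected components of the flagged
contact graph with at least one positive tumor and one positive immune
cell, tested by the same permutation machinery.

## Worked example

```r
library(phosnet)

# a synthetic prior network, a planted kinase-inhibition dataset, and the
# full phospho -> enrichment -> subnetwork path
net <- gen_prior_network(n_kinases = 6, n_substrates = 10,
                         edge_density = 0.25, seed = 42)
sim <- gen_perturbation_dataset(net, targets = "KIN01", effect_log2 = 3,
                                n_reps = 3, noise_sd = 0.1, seed = 42)
filt  <- impute_missing(filter_fragments(sim$fragments))
sites <- map_sites(filt, sim$proteome)
d     <- collapse_duplicate_sites(differential(filt, sites, "TRT_KIN01"))
sum(abs(d$log2fc) > 1 & d$fdr < 0.05)
#> [1] 27        # all 27 planted downstream sites pass |log2FC|>1, FDR<0.05

enr <- enrich(demultiplex(score_sites(d)), gen_signature_db(net),
              n_perm = 1000, seed = 1)
head(as.data.frame(enr)[order(enr$p), c("signature", "nes", "p", "overlap")], 2)
#>   signature       nes          p overlap
#> 4     KIN04 -2.779850 0.01335878       6
#> 1     KIN01 -2.729143 0.02380952      12
# negative NES: inhibiting KIN01 shuts its (and its downstream kinases')
# substrate sites down

s <- prune_redundant_paths(extract_subnetwork(
       annotate_network(net, enr, d, treatment = "TRT_KIN01")))
s
#> <subnetwork> 16 nodes, 22 edges (treatment: TRT_KIN01)
head(centralities(s), 2)
#>    node degree_centrality eigenvector_centrality n_subgraphs
#> 1 KIN01         0.6000000              1.0000000           1
#> 2 KIN02         0.2666667              0.5415349           1
# the inhibited kinase is the network hub: highest degree, eigenvector 1

# spatial branch: a 500-cell map with a planted tumor-immune attraction
m  <- gen_cell_map(500, c(tumor = 0.4, immune = 0.3, stroma = 0.3),
                   list(c("tumor", "immune")), strength = 5, seed = 7)
g  <- voronoi_neighbors(m$cells)
ia <- interaction_test(g, m$cells$phenotype, n_iter = 1000, seed = 1)
subset(as.data.frame(ia), call != "ns",
       c(phenotype_a, phenotype_b, observed, z, p, call))
#>   phenotype_a phenotype_b observed          z           p       call
#> 2      immune      stroma      150  -8.480124 0.001998002  avoidance
#> 3      immune       tumor      409   4.650302 0.001998002 attraction
#> 4      stroma      stroma      277  16.541112 0.001998002 attraction
#> 5      stroma       tumor      151 -13.028412 0.001998002  avoidance
#> 6       tumor       tumor      290   5.743678 0.001998002 attraction
```

The planted tumor–immune attraction is recovered (Z = 4.65, p = 0.002);
stroma, excluded from the niches, self-clusters by displacement and avoids
both partners — the usual geometric side effect of co-clustering two
phenotypes in shared niches.

The whole pipeline also runs end-to-end from a config, writing every
artifact plus a manifest with md5 hashes and seeds:

```r
run_pipeline(default_config(seed = 1), "demo_out")
```

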