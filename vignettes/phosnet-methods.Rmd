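---
title: "Models and methods behind phosnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phosnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosnet)
```

phosnet reconstructs patient-level kinase signaling networks from
inhibitor-perturbation phosphoproteomics and quantifies heterocellular
spatial organization in imaging-mass-cytometry (IMC) cell maps. This
vignette explains each model, its assumptions, the tunable parameters, and
the deliberate choices made where a published procedure leaves the details
open. Nothing stated here goes beyond what the package's tests and the
`scripts/acceptance.R` script themselves compute.

## 1. From DIA fragments to phosphosite statistics

DIA (SWATH-type) phosphoproteomics quantifies each phosphopeptide through
several MS2 fragment ions. `filter_fragments()` applies the reliability
filters in a fixed, documented order:

1. **Absolute intensity.** Values not strictly above `min_intensity = 2000`
   become missing. The boundary is strict: an intensity of exactly 2000 is
   removed, 2001 is kept.
2. **Detection count.** A fragment must be detected at least
   `min_detected_per_condition = 2` times in at least one condition.
3. **Coherence.** Fragments of one peptide should agree up to a constant
   offset. A fragment is dropped when its log2 profile correlates below
   `min_corr = 0.25` with the per-sample median profile of its peptide, or
   when its mean log2 intensity sits more than `sd_factor = 2` standard
   deviations from the peptide consensus (the mean of the fragment means).
   The upstream tool this step emulates does not publish its internal
   definitions, so these are phosnet's own, and they are applied
   *iteratively to a fixed point*: after a fragment is removed the consensus
   is recomputed and the rule re-applied until nothing changes. The fixed
   point makes the whole filter idempotent — filtering a filtered table is a
   no-op — which is asserted by a property test.
4. **Fragment count.** Peptides keeping fewer than `min_fragments = 5`
   fragments are dropped entirely.

Missing replicate values are then imputed per fragment as 20% of that
fragment's minimum observed intensity (`impute_missing()`); observed values
are never touched, and fragments with no observation at all cannot be
imputed and are dropped with a warning.

`map_sites()` locates each peptide in its protein and converts peptide
phospho-offsets to 1-based protein coordinates. The protein sequence is
authoritative for the residue letter. Peptides matching more than once use
the first occurrence and are flagged; peptides not found are excluded and
reported.

`differential()` rolls fragments up to peptides by summing fragment
intensities per sample, takes log2, and tests treatment against control
with a two-sample Welch t-test per site, reporting
log2FC = mean(log2 treatment) − mean(log2 control) and
Benjamini–Hochberg FDR across the sites of a treatment. This simple,
transparent test replaces a model-based external tool on purpose: the
published analysis states its filter parameters but not a reproducible
test, and the replacement is named in the output so no reader mistakes it
for the original. Two degenerate conventions are documented: when both
groups have zero variance, p is 1 for equal means and 0 otherwise.
`collapse_duplicate_sites()` keeps, per phosphosite, the peptide with the
larger mean control signal (ties: lexicographically smallest peptide id)
and recomputes BH over the retained rows so reported FDRs always refer to
the reported site set.

## 2. Site-centric signed enrichment

Kinase activities are inferred from the phosphosite statistics by a
site-centric, direction-aware running-sum enrichment
(`score_sites()`, `demultiplex()`, `enrich()`).

Input scores are fold-change-signed log10-transformed FDRs,
`sign(log2FC) · (−log10 max(FDR, floor))`, with a default floor of 1e−10 so
scores stay finite. Records from multiply-phosphorylated peptides are
demultiplexed to their constituent single sites, keeping the larger
|score| on collisions.

All measured sites are ranked by descending score. For a signature with
member contributions $c_j = d_j |s_j|^w / \sum_k |s_k|^w$ (direction
$d_j = +1$ for "u", $-1$ for "d"; weight $w = 1$ by default), the running
statistic adds $c_j$ at each member position and subtracts
$\sum_j c_j / (n - m)$ at each of the $n - m$ non-member positions. The
balancing decrement makes the running sum end exactly at zero; for
all-up signatures this is the classic Kolmogorov–Smirnov-style form, and
for mixed-direction signatures it is what makes the enrichment score an
odd function of the input scores (negating every score negates every ES
exactly, up to float roundoff — a tested invariant).

The enrichment score is, by default, the *area under the running
enrichment statistic*: its mean over all rank positions. The classic
maximum-deviation statistic is available with `es_type = "max"`; the
default is recorded in the result's attributes because the upstream
tool's precise normalization is not published. Down-direction sites flip
their member contribution only — the global ranking is never altered.

Significance comes from site-label permutations (the site-to-score
assignment is shuffled, matching a single-sample site-centric design):
NES = ES / mean(|ES′|) over same-sign permuted scores ES′, the
permutation p is the same-sign fraction with |ES′| ≥ |ES| (floored at one
permutation), and FDR is BH within each signature category by default
(mirroring separate result panels per category), with a global option.
The default `n_perm = 1000` is a desk-scale choice — the reference
analysis used 1e5 — and the count is stored with the result. A note on
tied scores: any rank-position statistic depends on where members land in
the tie-broken ranking, so equal input scores do *not* force equal ES
across same-size signatures; what holds, and is tested, is that identical
member positions give identical ES and that nothing looks significant
against the permutation null.

Under a global null (i.i.d. normal scores, random signatures) the
empirical type-I error at p < 0.05 sits inside the binomial 99% band over
500 signatures; an independent straightforward implementation of the
running sum reproduces every ES to < 1e−10 on instances of up to 50 sites.

## 3. Perturbation subnetworks on a prior causal network

The prior network is a directed, signed kinase–substrate graph in
SIGNOR-style TSV (`load_prior()`): self-loops are dropped, duplicate edges
merged with residue annotations unioned. `annotate_network()` writes
kinase-signature NES/FDR on nodes and phosphosite log2FC/FDR on edges
(the measured site with the smallest FDR represents an edge that carries
several residues); absent annotations stay `NA`, never 0.

`extract_subnetwork()` implements the reconstruction:

* **Perturbed nodes** have node FDR ≤ `node_fdr` (inclusive, default 0.05);
  **perturbed edges** have edge FDR ≤ `edge_fdr`.
* For every **ordered** pair of distinct perturbed nodes at directed
  shortest-path distance ≤ `max_path_len` (default 2 hops, unit edge
  weights), *all* shortest paths are collected. Direction matters because
  the prior is causal; an undirected mode exists behind a flag, and the
  choice is the conservative causal reading of a procedure whose
  published description does not state it.
* The union of path edges and perturbed edges (with endpoints, plus
  isolated perturbed nodes) forms the candidate graph, and the largest
  undirected connected component is returned. Ties are broken
  deterministically: larger total |NES|, then lexicographically smallest
  node set.
* Provenance (`perturbed_node` / `perturbed_edge` / `path_connector`) is
  recorded per element; perturbed status wins where both apply.

`prune_redundant_paths()` prefers, per pair, shortest paths whose every
edge carries a measured phosphosite; when at least one fully annotated
path exists, unannotated alternatives are removed provided their elements
are not perturbed and serve no other retained path, and any removal that
would disconnect the module is rolled back for that pair. The exact
pruning predicate of the published analysis is under-specified; this
reading is flagged in the documentation.

`merge_subnetworks()` unions treatment subnetworks into a per-sample
network, keeps per-treatment annotations side by side (never averaged)
and counts `n_subgraphs` per node. `centralities()` works on the
undirected simple projection: degree/(n−1) and eigenvector centrality by
shifted power iteration ($A + I$, tolerance 1e−10, max-normalized). The
shift leaves eigenvectors unchanged but makes the dominant eigenvalue
strictly largest on connected graphs, so the iteration cannot oscillate
on bipartite structures such as stars. Single nodes get eigenvector 1 by
convention; in disconnected merged graphs the eigenvector concentrates on
the dominant component. `mutation_enrichment()` tests coding-mutation
overrepresentation among subnetwork nodes against the rest of the prior
with a two-sided Fisher's exact test (point-probability summation, the
mainstream convention — on a [[3,1],[1,3]] table this gives 34/70, and on
a fully concordant 5/5 split 2/C(10,5), i.e. both extreme diagonals).

The whole extraction is validated element-for-element against an
exhaustive brute-force enumeration (explicit 1- and 2-hop path scan, BFS
component search, same tie-breaks) on 200 random annotated graphs.

## 4. Spatial statistics on IMC cell maps

A `cell_map` is the post-segmentation table: centroids in µm inside a
known ROI frame (the reference tile is 1000×1000 µm), a phenotype label,
and per-marker positive-area fractions. Marker positivity uses an
inclusive 10% area threshold; densities are counts over the frame area in
cells/mm².

**Voronoi neighborhoods.** `voronoi_neighbors()` computes, in C++, every
cell's Voronoi polygon as the intersection of half-planes (the bisectors
against all other sites) clipped to the ROI frame, tracking which site
each polygon edge came from. Two cells are neighbors iff they share a
boundary segment of positive length after clipping — point contacts are
excluded, so the center of a 3×3 lattice has exactly its 4 lateral
neighbors. Clipping to the frame is what prevents unbounded border cells
from generating spurious long-range adjacencies. Duplicate coordinates
are jittered by 1e−6 µm with a seeded RNG; collinear inputs are refused
with guidance. The adjacency is validated against an independent
scipy/shapely oracle (Delaunay-dual ridges clipped to the frame) on 100
random point sets.

**Attraction/avoidance.** `interaction_test()` counts, per unordered
phenotype pair (same-type pairs included), the neighbor edges joining the
two phenotypes, and builds the null by permuting phenotype labels over
the fixed positions (1000 iterations by default; label counts conserved
by construction). Z standardizes the observed count by the null moments.
The p value is two-sided: twice the smaller permutation tail with an
add-one correction, capped at 1. A sign-directed one-sided p (choosing
the tail after looking at Z) would double the nominal flag rate under
complete spatial randomness and break the calibration this test must
satisfy; the two-sided form keeps the p < 0.01 flag rate inside the
binomial 99% band in a 100-map calibration run. Calls use the |Z| > 2
and p < 0.01 convention; the thresholds are configurable, and pairs with
a degenerate null (zero SD) are flagged rather than called.
`stouffer_combine()` aggregates per-ROI Z scores into a cohort Z as
ΣZ/√k.

**Microaggregates.** `microaggregates()` restricts the neighbor graph to
PDL1+ tumor and PD1+ immune cells and keeps connected components
containing at least one of each. `microaggregate_test()` permutes both
flag vectors independently over the fixed positions and compares the
qualifying-component count to its null. Note the statistic is
non-monotone in flag density: very dense flags merge aggregates into few
components, so the informative regime — and the planted power scenario in
the tests — is rare checkpoint-positive populations in tight contact
niches.

## 5. Protein-complex co-abundance and mRNA–protein correlation

`complex_coabundance()` scores each complex with ≥ 5 measured members by
the mean Pearson correlation over all member pairs across samples
(pairwise-complete; pairs sharing < 3 samples are skipped and logged).
Complexes are ranked and partitioned into quartile classes with
⌈N/4⌉ complexes per tail and deterministic tie-breaks by complex id.
Because the source material labels the tails inconsistently, phosnet
defines **stable = highest mean correlation** and labels the classes
explicitly rather than as "top/bottom". `subunit_variance()` uses the
unbiased (n−1) variance over observed values, `NA` below two
observations. `gene_wise_correlation()` computes per-gene Pearson
correlation between log2 mRNA and log2 protein over name-matched samples,
requiring ≥ 4 paired observations per gene. Correlation is invariant to
per-feature affine rescaling and to sample order — both tested; note that
*per-sample* affine maps do change cross-sample correlations, so no such
invariance is claimed.

## 6. The synthetic-data generators

Every pipeline input has a seeded generator with a ground-truth sidecar,
so all downstream stages are testable without any external data. All
randomness is funneled through one seeded local-RNG helper; the caller's
RNG state is never disturbed, and a seed fully determines every output
byte (tested).

* `gen_prior_network()` draws a weakly connected, signed, residue-annotated
  kinase/substrate graph (connectivity by a kinase-rooted spanning
  structure plus random extra edges; residue positions unique per target
  so each annotated site maps to one edge). Signs are 75% activating.
* `gen_signature_db()` derives one kinase signature per node from its
  outgoing edges, direction "u" on activating and "d" on inhibiting edges.
* `gen_perturbation_dataset()` emulates replicated DIA intensities:
  per-fragment log2 baselines N(12, 1) (so the absolute filter at 2000
  removes a real tail), per-sample loading offsets (sd 0.3) and
  per-peptide biological wobble (sd 0.15) that make fragments of a peptide
  coherent (giving the correlation filter something meaningful to
  measure), replicate noise `noise_sd`, and a 5% fragment dropout.
  Sites on edges ≤ 2 hops downstream of each inhibited kinase shift by
  `effect_log2` with sign opposite the net edge effect. Planted peptides
  draw baselines from the upper tail (≥ 11.5 log2) so the perturbed sites
  stay quantifiable in the control arm — emulating well-measured inhibitor
  targets, and required for the planted truth to be recoverable at all.
* `gen_cell_map()` realises attraction pairs as a **bivariate Thomas
  process with shared parents**: ~6 parent locations per mm², and each
  cell of either paired phenotype moves, with probability
  strength/(1+strength), to a Gaussian displacement (sd 15 µm, about a
  cell diameter) from a shared parent. Co-clustering around common niches
  is the standard linked-Cox reading of cross-type attraction and is what
  raises the mutual Voronoi contact count far above chance; strength 0
  reduces exactly to complete spatial randomness. A self-pair gives the
  univariate Thomas process.
* `gen_complex_abundance()` gives complex subunits an equicorrelated
  structure (shared latent factor, pairwise correlation ρ);
  `gen_mutations()` mutates genes independently at a fixed rate.

What the generators deliberately do **not** emulate: raw spectra or
peak-picking artefacts, retention-time drift, isotope interference,
segmentation errors or marker spillover in IMC, and batch structure
across samples. Green tests therefore demonstrate correctness of the
statistics and algorithms under the stated generative assumptions, not
robustness to those upstream artefacts.

## 7. Problem sizes, numerics and degenerate inputs

The test and acceptance runs use sizes chosen for a single desk CPU:
200 random graphs (≤ 30 nodes) for the extraction oracle, 50 seeded
perturbation datasets (10 kinases, 15 substrates, effect 3, noise 0.1,
3 replicates), 100 enrichment oracle instances (≤ 50 sites) plus a
500-signature null at 1000 permutations, 100 calibration maps and 50
power maps (500 cells, 1000 permutations), 30 microaggregate maps
(1500 cells), and 100 Voronoi oracle point sets. These sizes keep every
property estimate inside its stated statistical band while the whole
suite runs in a few minutes.

Numerical conventions collected in one place: log base 2 for abundances
and fold changes throughout; FDR floored at 1e−10 before log10; power
iteration tolerance 1e−10; Voronoi minimum shared-boundary length 1e−6 µm
(positive length up to roundoff); permutation p values never exactly 0
(add-one); BH never decreases a p value past 1. Degenerate inputs have
defined behaviour rather than crashes: empty fragment tables pass
through, all-missing fragments are dropped with a warning, single-node
graphs get degree 0 and eigenvector 1, single-phenotype maps yield
flagged degenerate interaction rows, and an annotation-free network
yields an empty subnetwork with a warning.

## 8. Known limitations

* The differential engine is a deliberate, named substitution for the
  original model-based tool; absolute FDR values are not comparable to it.
* The enrichment area statistic is one documented reading of an
  under-specified normalization; the max-deviation alternative is exposed.
* Shortest paths are directed by default; if the published analysis used
  undirected paths its modules may differ, which is why both modes exist.
* The spatial permutation null conditions on the realised geometry; it
  tests label exchangeability, not the point process itself.
* Eigenvector centrality on disconnected merged networks reflects the
  dominant component only.
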