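---
title: "Methods: community ecology and network analysis of phyllosphere mycobiomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community ecology and network analysis of phyllosphere mycobiomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyllocore)
```

`phyllocore` implements the downstream statistical analysis of fungal
metabarcoding surveys of leaf surfaces: given an OTU read-count table, sample
metadata and a guild lookup table, it quantifies community structure
(transformations, dissimilarities, ordination, dispersion tests), builds
similarity and co-occurrence networks, extracts occupancy-defined core
mycobiomes nested across a sampling hierarchy, screens core taxa for
antagonistic (negatively correlated) pairs, and summarizes trophic modes and
shared/unique taxon sets. Because raw sequencing data are not needed to
exercise any of this logic, the package ships a synthetic-community generator
whose planted structure every stage must recover; the test suite and the
analysis scripts are built around that recovery loop.

## Data model

An `abundance_table` couples an integer read-count matrix (taxa as rows,
samples as columns) with one taxonomy record per taxon. Counts must be
non-negative integers: the upstream OTU pipeline produces reads, and
relative-abundance inputs are rejected so that every normalization in the
package is explicit and auditable. Taxonomy strings are parsed from the
UNITE-style `k__...;p__...;g__...` dialect, from plain binomials, or from bare
genus names; anything else — notably placeholder labels such as
`"Ascomycota sp. 52-1"`, which routinely name unresolved but biologically real
OTUs — is kept opaque with all ranks unknown and the source string preserved
verbatim, so such labels survive round trips and can still anchor core-set
membership. Files are plain TSV with a header row; tab characters inside
fields are rejected rather than quoted. Tables are taxa-as-rows by default
(the common OTU-table convention) with an explicit `transpose` flag for the
other orientation, and the taxonomy column name is configurable because no
standard header exists in the wild. We assume tables hold raw (unrarefied)
reads; no rarefaction step is offered.

## Transformations and dissimilarities

`hellinger_transform()` is the square root of relative abundance; each sample
column then has unit Euclidean norm, which tempers the dominance of abundant
taxa in downstream distances. `bray_curtis_matrix()` computes
BC(i, j) = Σ|x−y| / Σ(x+y) (delegated to `vegan::vegdist`) on raw counts by
default — Hellinger input is an explicit option, not the default, matching the
convention of general-purpose ecology software that computes Bray–Curtis
straight from the abundance table. `jensen_shannon_matrix()` uses base-2
logarithms by default so values are bounded in [0, 1], with 0·log 0 = 0; no
square-root metric variant is applied.

`pcoa()` is classical scaling: the Gower-centered −½D² matrix is
eigendecomposed, axes with eigenvalues above a relative tolerance of 1e−8
become coordinates, and negative eigenvalues (present whenever the
dissimilarity is not Euclidean-embeddable, as for Bray–Curtis and JSD) are
reported but excluded from coordinates. On Euclidean-embeddable input the
embedding reproduces the distances to 1e−8, which the tests assert.

## PERMDISP

`permdisp()` tests whether groups differ in multivariate dispersion. Samples
are embedded by principal coordinates keeping the negative-eigenvalue axes;
the squared distance of a sample to its group centroid is the real-part
contribution minus the imaginary-part contribution, floored at zero (the
standard correction for semi-metric dissimilarities). The observed statistic
is the one-way ANOVA F on those distances — it matches
`vegan::betadisper(type = "centroid")` exactly, which the tests cross-check.
The permutation scheme permutes group labels and recomputes centroids and
distances for every permutation, with
p = (1 + #{F_perm ≥ F_obs}) / (1 + n_perm) and a mandatory seed; the default
is 999 permutations. Group centroids (not spatial medians) are used. Constant
distance vectors yield F = 0 by convention. Because permutation p-values live
on the lattice k/(n_perm+1), the exact size-α rejection rule is p ≤ α; the
calibration experiments use that rule, and under the null generator the
empirical size at α = 0.05 with 199 permutations is verified to sit inside
[0.03, 0.07] over 500 simulated datasets (2 groups × 15 samples), with power
above 0.9 against a 3× dispersion ratio at 20 samples per group.

## Correlation screening

`spearman_screen()` ranks taxa by total abundance (ties broken
lexicographically by taxon id), keeps the top 100 by default — the usual
display convention for correlation panels — and computes Spearman's ρ with
average ranks for ties. Two-sided p-values use the t approximation
t = ρ√((n−2)/(1−ρ²)); an exact permutation null is impractical at the
15–45 sample sizes these surveys have, and the t approximation is standard at
n ≥ ~10. The default α = 0.01 on raw p-values mirrors how such screens are
reported in this literature; Benjamini–Hochberg adjustment is available.
Constant taxa are excluded and listed in a diagnostics field rather than
producing NaNs. `antagonism_screen()` restricts the screen to a candidate set
(typically the strict core) and returns only significant negative pairs,
sorted most-negative first.

## Similarity networks and the critical threshold

`to_similarity_matrix()` maps a normalized dissimilarity to integers:
S = round((1−d)·100). "Round to the nearest integer" does not disambiguate
halves; the default is half-up (the common spreadsheet convention), with IEEE
half-even as an option. `threshold_graph()` connects i and j iff S(i, j) ≥ t —
a pair with similarity exactly 33 is connected at threshold 33 — and retains
isolated nodes so sample counts are conserved. `sweep_thresholds()` builds all
101 graphs; edge sets are nested in t and per-step losses telescope, two laws
the tests fuzz.

Selecting the "critical" network — the single threshold whose graph is most
informative — requires a notion of distance along the sweep. We provide three
curves. `consecutive` is the normalized per-step edge loss
|E(G_t) Δ E(G_{t+1})|/C(n,2); `from_initial` is the monotone
|E(G_0) Δ E(G_t)|/C(n,2). Both are transparent but neither captures *where the
network's connectivity breaks*: when between-group similarities spread over a
few adjacent integers, the raw edge-loss maximum can sit one step before the
graph actually disconnects, returning a graph that still straddles groups.
The default for `find_critical_network()` is therefore `fragmentation`: the
normalized drop in the size of the largest connected component,
D(t) = (S(t) − S(t+1))/n. This is a percolation-style criticality measure —
the threshold where the network fragments most is, in percolation terms, the
critical point of the sweep — and on planted two-block similarity matrices
(within-block 94–96, between-block 49–51) it provably selects the
disconnection step, so the critical graph has exactly the planted blocks as
components in every run; the acceptance suite asserts 100/100. The curve
method is recorded alongside the result for provenance, ties break towards
the smallest threshold, the critical graph is G_{t*+1} for the step-wise
methods (the sparser side of the drop), and an identically-zero curve returns
t* = 0 with a degenerate-sweep warning.

`modularity_partition()` maximizes Newman–Girvan modularity with igraph's
fast-greedy (default, deterministic) or Louvain algorithm under a caller
seed; if the heuristic returns a partition worse than the trivial single
community, the trivial partition (Q = 0) is returned instead, so the result
is never worse than no partition at all. Edgeless graphs get one community
per node, Q = 0, with a warning.

## Co-occurrence networks and core extraction

`to_incidence()` binarizes at `min_count = 1` read by default — the only
choice consistent with read-count OTU tables that carry no explicit presence
threshold — and the threshold is configurable to guard against index-hopping
noise. `cooccurrence_graph()` joins two taxa when at least one selected
sample contains both, recording the witnessing samples on each edge; the
graph equals the union of per-sample cliques, the oracle the tests compare
against. The sampling unit for cores is the sequenced unit (a leaf pool or
an individual leaf); `aggregate_samples()` ORs leaves into a tree-level unit
for intra-individual analyses, supporting both readings of "present in all
sampled individuals".

`core_taxa()` applies an occupancy cutoff (fraction of group samples where a
taxon is present); the default 1.0 is the strict core. For nested sample
groups A ⊆ B, occupancy-1 cores satisfy core(B) ⊆ core(A) — a theorem, which
`hierarchical_cores()` nevertheless re-checks per parent/child pair and
reports; a non-empty nesting report indicates an implementation bug, never a
data property, and the suite fuzzes the theorem over hundreds of random
tables.

## Guilds and set algebra

`assign_guild()` matches taxonomy against a local lookup table at the most
specific available rank (species > genus > family > order > class > phylum),
mirroring the documented precedence of the standard fungal guild tool; the
table is consumed as a static TSV snapshot, never queried live, and the
bundled `inst/extdata/guild_db_synthetic.tsv` is a small synthetic
snapshot-style fixture, not an excerpt of any real database. Records may
carry mode combinations ("Pathotroph-Saprotroph"), which are kept as sets
and reported as literal combination categories. Unassigned is a value, not
an error. `trophic_mode_profile()` returns per-group probability vectors
over mode combinations (including unassigned), weighted by taxa or by
reads. `venn_partition()` enumerates all 2^k − 1 regions of 2–5 named sets
with exact memberships; label normalization is whitespace-trimming only —
synonym resolution is out of scope.

## The synthetic generator

`generate_dataset()` emulates the study design the pipeline targets: two
sites (CNF/TNF), five adult trees per site, one tree sequenced as five
individual leaves, and five plantlets at the second site — 19 sampling units
by default — at a fixed depth of 50,000 reads per sample. Relative abundances
are log-normal per taxon with per-sample log-normal perturbations
(multiplicative overdispersion), and reads are drawn multinomially at the
stated depth, so column sums are exactly the depth. Design choices:

* **Planted cores.** Each core taxon has a home node in the hierarchy
  (all ⊇ adults ⊇ site-adults; all ⊇ plantlets) and is present in every home
  sample; the multinomial draw is rejected and resampled in the rare event a
  planted taxon receives zero reads. Every other taxon — and every core
  taxon with respect to nodes outside its home — is *guarded* to miss at
  least one sample of each node it does not own. The guards make the strict
  cores exactly the planted sets, which is what turns core extraction into a
  scored recovery test rather than a smoke test.
* **Antagonists.** One focal taxon and two partner taxa share a latent
  factor with opposed signs on the log scale (a monotone coupling, which is
  what a rank correlation target requires), plus per-taxon noise. The noise
  scales were set once, from the closed-form normal-score relation between
  Pearson and Spearman correlation followed by a pilot simulation to absorb
  the compositional and multinomial attenuation, and then frozen at values
  that realize mean Spearman ρ ≈ −0.60 and −0.54 at 45 sampling units. The
  per-replicate spread of an estimated ρ at n = 45 is ≈ 0.1 regardless of
  the construction (the Fisher-information floor), so recovery targets are
  stated for replicate means and detection rates, not single draws.
* **Stage shift.** A four-taxon group (an Exobasidiales-like family in the
  taxonomy strings) is enriched 8-fold in plantlet intensities before
  renormalization, planting the adult/plantlet dominance contrast; after
  compositional renormalization the realized read-share ratio is
  necessarily below the nominal fold.
* **Trophic modes.** Modes are drawn per taxon at 55% saprotroph, 10%
  pathotroph, 2% symbiotroph; taxa with placeholder names can never be
  matched in a guild table, so assignable taxa are upweighted to keep the
  community-wide fractions at their nominal values, genera share their
  first-drawn mode, and the realized per-taxon modes are recorded in the
  truth record so profile recovery can be asserted exactly.

`generate_block_similarity()` plants a two-block integer similarity matrix
with non-overlapping within/between ranges (94–96 vs 49–51 by default),
giving the critical-network selector an unambiguous gap. `null_dataset()`
removes all structure — exchangeable samples, no couplings — for calibration
of test size and false-positive rates.

What the generator does **not** emulate: sequence-level artifacts (PCR bias,
chimeras, index hopping), taxon-taxon interactions beyond the planted trio,
spatial or temporal autocorrelation between trees, and realistic taxonomic
breadth. Passing the recovery suite therefore shows the *algorithms* are
correct under controlled conditions, not that any particular biological
finding generalizes.

## Problem sizes and determinism

The test and calibration runs use the generator defaults (19 samples at
depth 50,000; 45 samples for correlation calibration), 100–500 Monte-Carlo
replicates per calibration, and 199 permutations inside calibration loops
versus 999 in ordinary analyses — sizes chosen so the whole recovery loop
runs comfortably on a laptop while leaving Monte-Carlo error well inside the
asserted bands. Every stochastic stage requires an explicit seed, seeds are
restored after use (`with_seed()`), and `run_pipeline()` reruns to
byte-identical TSV outputs under an identical configuration, which the
acceptance suite checks literally.

## Known limitations

* The Spearman p-value is a t approximation; at fewer than ~10 samples it is
  coarse, and the screen refuses to run below 4.
* Jensen–Shannon and Bray–Curtis are semi-metrics; PCoA on them produces
  negative eigenvalues, handled but reported, and distances are not exactly
  representable in the returned coordinates.
* The fragmentation curve is the right default when group structure
  expresses itself as connectivity; for sweeps whose informative change is
  density rather than fragmentation, use `consecutive` and inspect the
  curve.
* Guild assignment is string matching at fixed ranks; synonymy,
  misspellings, and rank inconsistencies in real lookup tables must be
  resolved upstream.
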