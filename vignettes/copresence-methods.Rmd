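---
title: "Methods: phylogenetic co-occurrence profiling, donor-taxon inference and marker-anchored organelle assignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`copresence` bundles the three computational procedures used to discover
and characterise a mitochondrial pathway from comparative genomics and
fractionation proteomics: (i) phylome-style phylogenetic profiling that
finds protein families co-occurring with a marker gene set across a
panel of eukaryotic genomes, (ii) taxonomic assignment of the
prokaryotic ancestor of a eukaryotic gene family across a series of
progressively expanded homologue datasets, and (iii) assignment of
proteins to mitochondrial or peroxisomal clusters from density-gradient
fractionation intensities anchored on marker proteins. This vignette
documents the models behind each step, the tunable parameters, the
numerical choices, what the planted-truth simulators do and do not
emulate, and the known limitations.

## 1. Phylogenetic profiling

### Model

The profiling pipeline asks which protein families have the same
phyletic pattern as a marker pathway: present in the species that carry
the pathway ("positive" species), absent from species that confidently
lack it ("negative"), with a third class of "exempt" species whose data
are too incomplete (EST-only surveys, single-cell transcriptomes) for
their absences to be trusted.

The chain of steps is the classic phylome construction:

1. **All-vs-all search.** Every protein of every proteome is compared
   against all others by Smith–Waterman local alignment (BLOSUM62,
   affine gap open 11 / extend 1). Raw scores are converted to bits and
   E-values with the Karlin–Altschul approximation (gapped BLOSUM62
   parameters, lambda = 0.267, K = 0.041); hits with E-value above the
   cutoff (default 1e-5) are discarded. This internal search is meant
   for desk-scale data; for real proteome sets one runs BLAST and feeds
   the tabular output in, after which all downstream steps are
   identical.
2. **Per-seed gene trees.** Each gene seeds a neighbour-joining tree
   over its best `max_homologs` (default 15) hits. Distances are
   Kimura-corrected identity distances, `d = -ln(1 - D - 0.2 D^2)` with
   `D = 1 - identity`, with identity averaged over the two search
   directions; saturated pairs (D beyond the domain of the correction)
   are capped at distance 10. The collection of trees seeded from one
   species' genes is that species' phylome.
3. **Species-overlap orthology.** Each tree is midpoint-rooted and an
   internal node is labelled a duplication if the species sets of its
   child subtrees intersect, a speciation otherwise. A leaf is an
   ortholog of the seed exactly when their most recent common ancestor
   is a speciation node. No reference species tree is consulted.
4. **Network pooling and trimming.** Ortholog pairs from all phylomes
   are pooled into a network whose edge support counts the phylomes
   asserting the pair (at most 2, one per endpoint). Trimming first
   drops edges below a support threshold, then handles gene fusions: a
   node whose incident edges align to disjoint regions of it (pairwise
   interval Jaccard at or below a threshold, single-linkage grouping) is
   split into region-restricted sub-nodes, each edge reattached to the
   sub-node containing its alignment midpoint.
5. **Orthogroups and selection.** Orthogroups are the connected
   components of the trimmed network. A candidate family must have
   members in at least two positive species and none in any negative
   species; exempt species are ignored on both sides. Candidates are
   confirmed ("bona fide") only if, possibly after targeted re-search
   evidence ("rescue hits", ingested rather than computed), they cover
   every species of the required set.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `evalue_cutoff` | 1e-5 | search significance threshold |
| `max_homologs` | 15 | homologues per seed tree |
| `min_support` | 1 | minimum phylome support of a kept edge; 2 reproduces a stricter second-pass analysis |
| `fusion_jaccard_max` | disabled | interval-Jaccard threshold for fusion splitting |
| `min_positive` | 2 | positive species required of a candidate |

Two presets mirror the usual two-pass design: a permissive first pass
(`min_support = 1`) that favours sensitivity, and a second pass
(`min_support = 2`) requiring both endpoint phylomes to agree.

### Design notes

The published pipelines of this kind specify the architecture
(phylomes, pooled network, successive trimming, fusion handling) but
leave the individual rules to supplementary material; the rules
committed here — NJ on Kimura-corrected identities, MRCA species
overlap, support-count weights, interval-Jaccard fusion splitting — are
standard, defensible choices, each behind a parameter so alternatives
can be slotted in. Within-species paralogues are allowed: profiles
store member counts and presence means count ≥ 1. Note that two
independent same-species copies planted in a simulated family create
genuine duplication nodes and can legitimately fragment that family
under species overlap — this is the method working as designed, not a
defect of the implementation.

## 2. Donor-taxon inference

### Model

For a eukaryotic gene family of suspected prokaryotic origin, the
question is which prokaryotic taxon donated it. Because the answer is
notoriously sensitive to taxon sampling, the method re-asks the
question over a series of nested homologue datasets: with `s_best` the
best prokaryotic homologue bit score, dataset `c` keeps every
eukaryotic seed plus all prokaryotic homologues with score
`>= c * s_best`, for `c` on the inclusive grid 0.99, 0.98, ..., 0.70.
Smaller `c` admits more distant homologues, so the datasets are nested.

Each dataset's tree (inferred externally in production; here the
simulated or NJ tree restricted to the dataset members) is processed
as:

1. **Rooting between domains.** If an edge of the unrooted tree
   separates all eukaryotes from all prokaryotes, the tree is rooted at
   that edge's midpoint and the support label attached to it is
   recorded. If no such edge exists the eukaryotes are not
   monophyletic on that tree; the run is recorded as unusable, carrying
   the conflicting leaves, and the analysis continues.
2. **Proportional node taxonomy.** Over the prokaryotic subtree only,
   from the leaves to its deepest node, each node receives a
   probability vector over prokaryotic taxa (phylum or class): a leaf
   is an indicator of its own taxon, an internal node the average of
   its children's vectors. Branch lengths are ignored — the rule is
   about nodes, not time.
3. **Parental assignment.** The distribution at the deepest prokaryotic
   node (the prokaryotic child of the root) is the answer; its argmax
   is the top taxon, with exact ties reported as "unresolved".
4. **Stability.** Across the grid, the modal top taxon among usable
   (eukaryote-monophyletic) runs and its frequency summarise how stable
   the inference is.

### Design notes

- "Proportionally considering the descending nodes" admits two
  readings: equal weight per child node (children-mean) or weight by
  descendant leaf counts (leaf-frequency). Both are implemented
  (`node_weighting = "children"` or `"leaves"`); children-mean is the
  default because the rule is phrased in terms of nodes rather than
  leaves. The two give different answers on asymmetric trees — e.g. a
  subtree `(alpha, (beta, beta))` yields 0.5/0.5 under children-mean
  but 1/3 vs 2/3 under leaf-frequency — and the test suite pins both.
- Cutoff comparison is inclusive (`>=`), and grid values are rounded to
  2 decimals before use so floating-point drift cannot change dataset
  membership.
- No bootstrap threshold is applied by default; support values are
  reported verbatim and a minimal-support check is available as an
  option (`test_eukaryote_monophyly(min_support=)`), returning an
  indeterminate verdict when the tree carries no support labels.
- Maximum-likelihood tree inference, model selection and bootstrapping
  are out of scope: the package consumes trees.

## 3. Marker-anchored organelle assignment

### Model

Density-gradient fractionation yields, for every protein, a profile of
label-free intensities over three gradient fractions (named Opt1015,
Opt1520, Opt2030 after their density steps) in five biological
replicates. Co-fractionating proteins share profiles, so organelle
residence can be read off profile clusters anchored on marker proteins
— the LOPIT idea. The workflow:

1. **Validity filter.** Keep proteins with at least `k = 2` valid
   values in at least one fraction (idempotent; removed proteins are
   reported as `not_quantified`).
2. **Log2 transform** (default on; disable for already-log data).
3. **Left-censored imputation.** Missing label-free values represent
   low-abundance measurements, so each missing cell of a column is
   drawn from `Normal(mean - 1.8 sd, (0.3 sd)^2)` with mean and sd from
   that column's observed values — the conventional downshifted
   imputation of proteomics practice (width 0.3, downshift 1.8, both
   configurable). Observed cells are never touched; the draw is
   reproducible from the seed.
4. **PCA.** Proteins are projected onto the first two principal
   components of the column-centred table. Components' signs are fixed
   by making each component's largest-magnitude loading positive, so
   runs are deterministic; the loadings are emitted alongside the
   scores.
5. **Marker clusters.** For each organelle, a robust Gaussian ellipse
   is fitted to its markers' PC coordinates: classical mean/covariance,
   drop the 10% of markers with the largest Mahalanobis distances,
   refit, and cut at the chi-square(2) quantile (default 0.99) of
   squared Mahalanobis distance.
6. **Calls.** Inside exactly one ellipse: that organelle. Inside both,
   or within a configurable relative margin of either boundary:
   ambiguous — boundary proteins cannot be assigned confidently.
   Inside neither: other.

### Coverage calibration of the cluster boundary

A plug-in chi-square ellipse systematically under-covers because it
ignores the estimation error of the fitted mean and covariance: for a
new point from the same Gaussian, the squared Mahalanobis distance to a
classical fit of `n` points is `p (n-1)(n+1) / (n (n-p)) F(p, n-p)`
distributed, not chi-square(p). With 26 markers the nominal 99% ellipse
would cover only ~97% of its own population. The covariance is
therefore rescaled by (i) the usual Gaussian consistency factor for the
trimmed scatter (as in MCD-type estimators) and (ii) the finite-sample
F factor above, evaluated at an effective sample size of `0.7 n`
because the trimmed covariance estimator carries ~1.4x the sampling
variance of the classical one at 10% trimming (Gaussian relative
efficiency ~0.7, measured by Monte Carlo). After calibration the
ellipse holds its nominal coverage at both marker-set sizes used here
(Monte-Carlo coverage 0.990–0.992 at n = 376 and n = 26).

### Numerical choices

- Near-singular marker covariances (collinear markers) are regularised
  by adding `1e-6 * mean(diag(S))` times the identity.
- A literal intensity of 0 is treated as measured by default
  (`zero_is_missing` flips this), since label-free exports differ in
  how they encode censoring; non-positive values are set to missing
  (with a warning) if the log2 transform is requested.
- Uniform rescaling of all raw intensities shifts every log2 column by
  the same constant, which both the imputation (same seed) and the
  column-centred PCA absorb: calls are invariant, and the test suite
  checks this.

## 4. What the simulators emulate — and what they do not

Each analysis has a planted-truth generator, a pure function of its
scenario object (seed included): equal scenarios give byte-identical
artifacts, and truth tables are emitted alongside.

**Profiles** (`simulate_proteomes_with_profiles`): families evolve on a
star phylogeny — one random ancestor per family, mutated independently
into each member species at 10% per branch (members ~81% identical);
decoys are unrelated random sequences. The default panel has 8
positive, 8 negative and 3 exempt species and five planted families
probing each selection rule (full presence; 2 positives + exempt;
4 positives + exempt; a single positive, below threshold; presence in a
negative species). The star phylogeny is the smallest model sufficient
for the profiler's correctness target (set-membership recovery); it
does not emulate realistic sequence evolution — no indels, no rate
heterogeneity, no shared tree structure — so passing tests show the
pipeline recovers clean planted families, not that it is robust to
alignment artefacts or deep divergence.

**Donor trees** (`simulate_donor_tree`): one random coalescent subtree
per phylum (default five phyla of five leaves), joined in random order
on a backbone; the eukaryotic clade (default three leaves) is grafted
three nodes deep inside the donor phylum's subtree, on a stem three
times the mean branch length (the long branch separating eukaryotic
genes from their prokaryotic relatives). Homologue bit scores decay
exponentially with path distance from the eukaryotic clade, anchored so
the best prokaryotic hit scores ~300 bits, which lets the 0.99–0.70
coefficient grid span realistic cutoffs. Real gene trees add
reconstruction error, long-branch artefacts and incomplete taxon
sampling that this generator does not model.

**Fractionation tables** (`simulate_fractionation_table`): the default
scale mirrors a whole-lysate quantification — 950 mitochondrial, 80
peroxisomal, 3168 other proteins (4198 total), with 376 mitochondrial
and 26 peroxisomal markers drawn from their classes. On the log2 scale
a cell is `class_mean[fraction] + protein offset (sd 0.5) + replicate
noise (sd 0.5)`; the class mean vectors are mito (21, 24, 27) —
enrichment grows towards the densest fraction — perox (23.5, 27.5, 22)
peaking mid-gradient, and other (27, 24.5, 22) for soluble material
depleted with density. Missingness is logistic in the true log2
intensity with slope −3 around ~21.5, i.e. a sharp detection limit:
censoring concentrates in each class's lightest fraction (~13% of
cells overall) so that imputed values land near the true low values,
which is what makes downshifted imputation appropriate. The generator
emulates left-censored MNAR missingness and class-specific enrichment,
not ratio compression, shared contamination structure, or
peptide-level effects.

## 5. Problem sizes used by the tests

The test suite runs the profiler end to end on 10 planted scenarios
(19 species, ~71 genes each), checks orthogroup extraction against a
transitive-closure oracle exhaustively on all graphs of up to 5 nodes
plus 400 random graphs up to 50 nodes, verifies donor recovery on 200
simulated trees, and measures organelle-assignment accuracy over 200
replicates at the full 4198-protein scale. These sizes keep the whole
suite within a couple of minutes on one core while leaving each
property statistically meaningful.

## 6. Known limitations

- The internal Smith–Waterman search with Karlin–Altschul statistics is
  a desk-scale stand-in for BLAST; its E-values are approximate and it
  is quadratic in total proteome size.
- Species-overlap orthology over NJ trees is sensitive to tree errors
  for deep or fast-evolving families; the network support threshold is
  the only guard.
- Whether phylome trees should be midpoint-rooted or seed-rooted before
  species-overlap labelling is not settled; midpoint rooting is used.
- The donor method reports proportions, not a probabilistic model of
  transfer; "stability across the grid" is descriptive, and on real
  families the expected outcome is often instability rather than a
  clean donor.
- Cluster boundaries are ellipses; organelles with curved or
  multi-modal profile clouds would need the multi-class LOPIT
  classifiers that are out of scope here.
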