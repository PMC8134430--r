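# copresence

Comparative-genomics and spatial-proteomics tools for discovering a
mitochondrial pathway: find the protein families that co-occur with a
marker gene set across eukaryotic genomes, ask which prokaryotic taxon
a eukaryotic gene family came from, and assign proteins to organelles
from density-gradient fractionation proteomics. The package is written
for molecular evolutionists and organelle proteomicists who need these
three analyses reproducible end to end, with planted-truth simulators
so every step can be validated without downloading any external data.

## What it computes

**Phylogenetic profiling** (`run_profile_pipeline`). From per-species
proteomes: all-vs-all Smith–Waterman search (BLOSUM62, affine gaps
11/1, Karlin–Altschul E-values; or ingest BLAST outfmt-6), a
neighbour-joining gene tree seeded from every gene (distances
`d = -ln(1 - D - 0.2D²)`, `D = 1 - identity`), species-overlap
orthology (a node is a duplication iff its child subtrees share
species; a leaf is an ortholog of the seed iff their MRCA is a
speciation), pooling into a support-weighted orthology network,
trimming (support filter, gene-fusion splitting by alignment-interval
Jaccard), orthogroups as connected components, and selection of
families with members in ≥ 2 pathway-positive species and none in any
negative species, exempt species ignored. Confirmed families must
cover all required species, optionally via targeted-search rescue
evidence.

**Donor-taxon inference** (`run_donor_pipeline`). For a eukaryotic
family with prokaryotic homologues scored in bits: nested datasets
keep all eukaryotes plus prokaryotes with
`score ≥ c · s_best` for `c = 0.99, 0.98, …, 0.70`; each dataset's
tree is rooted between the domains (midpoint of the separating edge),
eukaryote monophyly is recorded, and every node of the prokaryotic
subtree gets a probability vector over phyla/classes — a leaf is an
indicator, an internal node the mean of its children (leaf-frequency
weighting available). The distribution at the deepest prokaryotic node
is the donor assignment; the modal top taxon and its frequency across
the grid summarise stability.

**Organelle assignment** (`run_organelle_pipeline`). From a protein ×
(fraction, replicate) intensity table: keep proteins with ≥ 2 valid
values in one fraction, log2 transform, impute left-censored missing
values from `Normal(mean − 1.8·sd, (0.3·sd)²)` per column, project
onto the first two principal components, fit robust Gaussian ellipses
to the mitochondrial and peroxisomal marker proteins (10% trimmed
covariance, chi-square(2) boundary at the 0.99 quantile, with
consistency and finite-sample coverage calibration), and call every
protein mitochondrial / peroxisomal / ambiguous (inside both or on a
boundary) / other.

All three inputs can be simulated with planted truth:
`simulate_proteomes_with_profiles`, `simulate_donor_tree`,
`simulate_fractionation_table`.

## Worked example

The `analysis/` scripts run the three analyses over simulated inputs
and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_inputs.R --seed 1
Rscript analysis/02_phyletic_profiling.R
Rscript analysis/03_donor_inference.R
Rscript analysis/04_organelle_assignment.R
```

which prints:

```
proteomes: 71 genes across 19 species, 5 planted families + 50 decoys
donor tree: 28 leaves, euk clade of 3 nested in Alphaproteobacteria
intensity table: 4198 proteins x 15 samples, 12.8% missing cells
71 genes grouped into 55 orthogroups; 3 match the phyletic profile, 1 present in all required species
against planted truth: precision 1, recall 1 (qualifying families: 3)
30 nested datasets; 30 with monophyletic eukaryotes; modal donor taxon Alphaproteobacteria (stability 1)
planted donor: Alphaproteobacteria - recovered
4198 of 4198 proteins quantified; PC1+PC2 explain 84% of variance
calls: mitochondrial=943, other=3175, peroxisomal=80
accuracy on non-marker organelle truth: 0.992
```

Reading this: of the five planted families, exactly the three whose
profiles satisfy the ≥ 2-positive / 0-negative rule come back as
candidates (the family present in only one positive species and the
one leaking into a negative species are rejected), and only the family
planted in all eight required species survives confirmation. The donor
pipeline recovers the planted Alphaproteobacterial origin at every one
of the 30 nested datasets. The fractionation workflow quantifies all
4198 simulated proteins and calls 943 mitochondrial and 80 peroxisomal
— the mitochondrial cluster an order of magnitude larger than the
peroxisomal one, as in a real mitochondria-enriched gradient — with
99.2% accuracy against the planted non-marker truth.

A minimal API session:

```r
library(copresence)
sim <- simulate_donor_tree(hgt_scenario(seed = 1))
summ <- run_donor_pipeline(sim$tree, sim$homologs, sim$taxon_map)
summ
#> donor_summary: 30 datasets, 30 usable; mode taxon Alphaproteobacteria (stability 1.00)
```

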