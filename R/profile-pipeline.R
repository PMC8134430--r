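## End-to-end phylogenetic profiling: proteomes -> all-vs-all hits ->
## per-seed phylome trees -> pooled orthology network -> trimming ->
## orthogroups -> phyletic-profile candidates -> full-presence
## confirmation.

#' Run the phylogenetic-profiling pipeline
#'
#' Seeds a gene tree from every gene of every proteome (the per-species
#' phylomes), infers seed-centred ortholog pairs by the species-overlap
#' rule, pools them into a support-weighted network, trims it, extracts
#' orthogroups as connected components and selects those whose phyletic
#' profile matches the panel. Two presets mirror typical use: a
#' permissive first pass (`min_support = 1`) and a stricter second pass
#' (`min_support = 2`, both endpoint phylomes must agree).
#'
#' @param proteomes Data frame `id`, `species`, `seq`.
#' @param panel A [species_panel()].
#' @param hits Optional precomputed hit table (outfmt-6 columns, e.g.
#'   from BLAST); when `NULL`, [all_vs_all_search()] is run.
#' @param evalue_cutoff E-value cutoff for the internal search.
#' @param max_homologs Homologues per seed tree.
#' @param min_support Minimum phylome support of a kept edge.
#' @param fusion_jaccard_max Interval-Jaccard threshold for gene-fusion
#'   splitting, or `NULL` to disable.
#' @param min_positive Minimum positive-species count of a candidate.
#' @param rescue_hits Optional rescue evidence for
#'   [confirm_full_presence()].
#' @param declared_absent Panel species absent from the proteome set.
#' @return List with `hits`, `network`, `orthogroups`, `profiles`,
#'   `candidates`, `bona_fide`.
#' @export
run_profile_pipeline <- function(proteomes, panel, hits = NULL,
                                 evalue_cutoff = 1e-5, max_homologs = 15,
                                 min_support = 1, fusion_jaccard_max = NULL,
                                 min_positive = 2, rescue_hits = NULL,
                                 declared_absent = character()) {
  stopifnot(inherits(panel, "species_panel"))
  if (is.null(hits)) hits <- all_vs_all_search(proteomes, evalue_cutoff)
  else hits <- validate_hits(hits)
  species_of <- setNames(proteomes$species, proteomes$id)
  pair_sets <- lapply(proteomes$id, function(seed) {
    tr <- build_gene_tree(seed, hits, max_homologs)
    if (is.null(tr)) return(NULL)
    infer_ortholog_pairs(tr, species_of, seed_id = seed)
  })
  nodes <- data.frame(id = proteomes$id, species = proteomes$species,
                      stringsAsFactors = FALSE)
  net <- assemble_network(pair_sets, nodes = nodes)
  net <- trim_network(net, min_support = min_support,
                      fusion_jaccard_max = fusion_jaccard_max, hits = hits)
  og <- extract_orthogroups(net)
  cand <- match_phyletic_profile(og, panel, min_positive = min_positive,
                                 declared_absent = declared_absent)
  bona <- confirm_full_presence(og, cand, panel$required_all,
                                rescue_hits = rescue_hits)
  list(hits = hits, network = net, orthogroups = og,
       profiles = orthogroup_profiles(og), candidates = cand,
       bona_fide = bona)
}

#' Score recovered candidates against a planted truth table
#'
#' A planted family qualifies when its own species profile passes the
#' panel rules (at least `min_positive` positive species, no negative
#' species, exempt ignored). A candidate orthogroup counts as a correct
#' recovery only if its membership equals the planted family's gene set
#' exactly.
#'
#' @param result Output of [run_profile_pipeline()].
#' @param truth Truth table from [simulate_proteomes_with_profiles()]
#'   (`gene_id`, `family`, `species`; `NA` family = decoy).
#' @param panel The [species_panel()] used.
#' @param min_positive Candidate threshold used in the run.
#' @return List `precision`, `recall`, `n_candidates`, `n_qualifying`,
#'   `recovered` (character vector of recovered family names).
#' @export
evaluate_profile_recovery <- function(result, truth, panel, min_positive = 2) {
  fams <- split(truth$gene_id, truth$family)
  fam_species <- split(truth$species, truth$family)
  qualifying <- names(fams)[vapply(names(fams), function(f) {
    sp <- unique(fam_species[[f]])
    length(intersect(sp, panel$positive)) >= min_positive &&
      !length(intersect(sp, panel$negative))
  }, TRUE)]
  og <- result$orthogroups
  cand <- result$candidates$group_id[result$candidates$candidate]
  matched <- vapply(cand, function(g) {
    members <- og$gene_id[og$group_id == g]
    hit <- vapply(qualifying, function(f) setequal(members, fams[[f]]), TRUE)
    if (any(hit)) qualifying[which(hit)[1]] else NA_character_
  }, "")
  tp <- sum(!is.na(matched))
  list(precision = if (length(cand)) tp / length(cand) else NA_real_,
       recall = if (length(qualifying)) tp / length(qualifying) else NA_real_,
       n_candidates = length(cand), n_qualifying = length(qualifying),
       recovered = sort(matched[!is.na(matched)]))
}
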