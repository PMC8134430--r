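## Donor-taxon inference for eukaryotic genes of prokaryotic origin:
## nested homologue datasets on a bit-score coefficient grid, rooting
## between the domains, eukaryote-monophyly bookkeeping, bottom-up
## proportional node taxonomy over the prokaryotic subtree, and a
## stability summary across the grid.

#' Generate nested homologue datasets on a coefficient grid
#'
#' For each coefficient `c` on the inclusive grid from `c_hi` down to
#' `c_lo` in steps of `step` (values rounded to 2 decimals to avoid
#' floating-grid drift), the dataset keeps every eukaryotic seed plus all
#' prokaryotic homologues with score >= `c * best prokaryotic score`.
#' Smaller `c` gives a superset: the datasets are nested.
#'
#' @param homologs Data frame with columns `id`, `score` (bits), `domain`
#'   ("eukaryote"/"prokaryote"); extra columns pass through.
#' @param c_hi,c_lo,step Grid bounds and step (defaults 0.99, 0.70,
#'   0.01).
#' @return Data frame with one row per grid value: `c`, `cutoff`,
#'   `n_members`, and a list-column `members` of id vectors.
#' @export
generate_nested_datasets <- function(homologs, c_hi = 0.99, c_lo = 0.70,
                                     step = 0.01) {
  stopifnot(c_lo <= c_hi, step > 0)
  stopifnot(all(c("id", "score", "domain") %in% names(homologs)))
  if (any(!is.finite(homologs$score))) stop("scores must be finite")
  euk <- homologs$id[homologs$domain == "eukaryote"]
  prok <- homologs[homologs$domain == "prokaryote", , drop = FALSE]
  if (!nrow(prok)) stop("no prokaryotic homologue in the set")
  best <- max(prok$score)
  grid <- round(seq(c_hi, c_lo, by = -step), 2)
  members <- lapply(grid, function(cc) {
    c(euk, prok$id[prok$score >= cc * best])
  })
  data.frame(c = grid,
             cutoff = grid * best,
             n_members = lengths(members),
             members = I(members))
}

#' Root a gene tree between the eukaryotic and prokaryotic sequences
#'
#' If an edge of the unrooted tree separates all eukaryotic leaves from
#' all prokaryotic leaves, the tree is rooted at the midpoint of that
#' edge and the support label attached to it (the eukaryote-side node
#' label) is reported. Otherwise the eukaryotes are not monophyletic on
#' the tree: a non-separable record is returned carrying the prokaryotic
#' leaves entangled inside the smallest clade containing all eukaryotes,
#' so the run can be logged rather than aborted.
#'
#' @param tree Unrooted [ape::phylo] with >= 1 eukaryotic and >= 1
#'   prokaryotic leaf.
#' @param taxon_map Data frame `id`, `domain`, `taxon` covering all
#'   leaves.
#' @return A `rooted_gene_tree` list: `tree` (rooted phylo or `NULL`),
#'   `separable`, `euk_leaves`, `prok_leaves`, `euk_clade_support`
#'   (numeric or `NA`), `conflicting` (prokaryotic leaves inside the
#'   eukaryotic span when non-separable).
#' @export
root_between_domains <- function(tree, taxon_map) {
  taxon_map <- validate_taxon_map(taxon_map)
  dom <- setNames(taxon_map$domain, taxon_map$id)
  miss <- setdiff(tree$tip.label, taxon_map$id)
  if (length(miss)) stop("leaves missing from taxon map: ",
                         paste(miss, collapse = ", "))
  euk <- tree$tip.label[dom[tree$tip.label] == "eukaryote"]
  prok <- tree$tip.label[dom[tree$tip.label] == "prokaryote"]
  if (!length(euk) || !length(prok))
    stop("tree must contain both eukaryotic and prokaryotic leaves")
  if (is.null(tree$edge.length)) tree$edge.length <- rep(1, nrow(tree$edge))

  ## view the tree from a prokaryotic vantage: eukaryotes are separable
  ## iff they form a clade when the tree is rooted at any prokaryotic leaf
  base <- ape::root(tree, outgroup = prok[1], resolve.root = TRUE,
                    edgelabel = TRUE)
  if (length(euk) == 1) {
    mrca <- match(euk, base$tip.label)
    inside <- euk
  } else {
    mrca <- ape::getMRCA(base, euk)
    inside <- ape::extract.clade(base, mrca)$tip.label
  }
  if (!setequal(inside, euk)) {
    return(structure(list(tree = NULL, separable = FALSE,
                          euk_leaves = euk, prok_leaves = prok,
                          euk_clade_support = NA_real_,
                          conflicting = sort(setdiff(inside, euk))),
                     class = "rooted_gene_tree"))
  }
  ## support of the separating edge = label of the euk MRCA in the
  ## prokaryote-rooted view, read before re-rooting
  ntip <- length(base$tip.label)
  support <- NA_real_
  if (mrca > ntip && !is.null(base$node.label)) {
    lab <- base$node.label[mrca - ntip]
    if (!is.na(lab) && nzchar(lab)) support <- suppressWarnings(as.numeric(lab))
  }
  ## root at the midpoint of the separating edge (the edge above the
  ## eukaryote MRCA)
  stem <- base$edge.length[base$edge[, 2] == mrca]
  rooted <- phytools::reroot(base, node.number = mrca,
                             position = stem / 2)
  structure(list(tree = rooted, separable = TRUE, euk_leaves = euk,
                 prok_leaves = prok, euk_clade_support = support,
                 conflicting = character()),
            class = "rooted_gene_tree")
}

#' @export
print.rooted_gene_tree <- function(x, ...) {
  cat("rooted_gene_tree:", length(x$euk_leaves), "eukaryotic /",
      length(x$prok_leaves), "prokaryotic leaves;",
      if (x$separable) "rooted between domains" else
        paste("non-separable (", length(x$conflicting), "conflicting )"),
      "\n")
  invisible(x)
}

#' Test eukaryote monophyly of a rooted gene tree
#'
#' Monophyly holds iff rooting between the domains succeeded. When
#' `min_support` is given, the recorded support of the eukaryotic clade
#' must also reach it; a successful rooting without a support label is
#' then reported as indeterminate (`NA`) rather than pass or fail.
#'
#' @param rooted A `rooted_gene_tree`.
#' @param min_support Optional minimal support (same scale as the newick
#'   labels, e.g. ultrafast-bootstrap 0-100).
#' @return List `monophyletic` (`TRUE`/`FALSE`/`NA`) and `support`.
#' @export
test_eukaryote_monophyly <- function(rooted, min_support = NULL) {
  stopifnot(inherits(rooted, "rooted_gene_tree"))
  if (!rooted$separable)
    return(list(monophyletic = FALSE, support = NA_real_))
  if (is.null(min_support))
    return(list(monophyletic = TRUE, support = rooted$euk_clade_support))
  if (is.na(rooted$euk_clade_support))
    return(list(monophyletic = NA, support = NA_real_))
  list(monophyletic = rooted$euk_clade_support >= min_support,
       support = rooted$euk_clade_support)
}

#' Proportional taxonomy of every node of the prokaryotic subtree
#'
#' Starting from the leaves and moving to the deepest node of the
#' prokaryotic subtree, each node receives a probability vector over
#' prokaryotic taxa (phylum or class tokens from the taxon map). A leaf
#' is an indicator of its own taxon. An internal node mixes its
#' descendants proportionally; with `node_weighting = "children"` (the
#' default) each child node contributes equally, with `"leaves"` each
#' child is weighted by its number of descendant leaves (equivalent to
#' the leaf-frequency distribution). Branch lengths are ignored: the
#' rule is about tree nodes, not time.
#'
#' @param rooted A separable `rooted_gene_tree`.
#' @param taxon_map Data frame `id`, `domain`, `taxon`.
#' @param node_weighting `"children"` or `"leaves"`.
#' @return A `taxon_distribution`: list with `tree` (the prokaryotic
#'   subtree), `dist` (matrix nodes x taxa; rows ordered tips first then
#'   internal nodes), `root_row` (index of the deepest prokaryotic
#'   node).
#' @export
assign_node_taxonomy <- function(rooted, taxon_map,
                                 node_weighting = c("children", "leaves")) {
  stopifnot(inherits(rooted, "rooted_gene_tree"), rooted$separable)
  node_weighting <- match.arg(node_weighting)
  taxon_map <- validate_taxon_map(taxon_map)
  taxon_of <- setNames(taxon_map$taxon, taxon_map$id)

  tree <- rooted$tree
  ntip <- length(tree$tip.label)
  rootn <- ntip + 1L
  kids_root <- tree$edge[tree$edge[, 1] == rootn, 2]
  prok_child <- kids_root[vapply(kids_root, function(ch) {
    tips <- if (ch <= ntip) tree$tip.label[ch]
            else ape::extract.clade(tree, ch)$tip.label
    all(tips %in% rooted$prok_leaves)
  }, TRUE)][1]
  if (is.na(prok_child)) stop("no prokaryotic root child found")

  if (prok_child <= ntip) {
    leaf <- tree$tip.label[prok_child]
    tax <- taxon_of[leaf]
    if (is.na(tax) || !nzchar(tax)) stop("leaf missing taxon: ", leaf)
    dist <- matrix(1, 1, 1, dimnames = list(leaf, unname(tax)))
    sub <- NULL
    root_row <- 1L
  } else {
    sub <- ape::extract.clade(tree, prok_child)
    tax <- taxon_of[sub$tip.label]
    bad <- is.na(tax) | !nzchar(tax)
    if (any(bad)) stop("leaf missing taxon: ",
                       paste(sub$tip.label[bad], collapse = ", "))
    taxa <- sort(unique(unname(tax)))
    stip <- length(sub$tip.label)
    nn <- stip + sub$Nnode
    dist <- matrix(0, nn, length(taxa),
                   dimnames = list(NULL, taxa))
    for (i in seq_len(stip)) dist[i, tax[i]] <- 1
    nleaves <- integer(nn)
    nleaves[seq_len(stip)] <- 1L
    ord <- ape::reorder.phylo(sub, "postorder")$edge
    for (nd in unique(ord[, 1])) {
      ch <- ord[ord[, 1] == nd, 2]
      w <- switch(node_weighting,
                  children = rep(1, length(ch)),
                  leaves = nleaves[ch])
      w <- w / sum(w)
      dist[nd, ] <- colSums(dist[ch, , drop = FALSE] * w)
      nleaves[nd] <- sum(nleaves[ch])
    }
    rownames(dist) <- c(sub$tip.label, paste0("node", seq_len(sub$Nnode)))
    root_row <- stip + 1L
  }
  structure(list(tree = sub, dist = dist, root_row = root_row,
                 node_weighting = node_weighting),
            class = "taxon_distribution")
}

#' Taxonomic assignment of the parental prokaryotic node
#'
#' Reads the distribution at the deepest node of the prokaryotic subtree
#' (the prokaryotic child of the between-domains root) and reports the
#' top taxon. Exact ties are reported as `"unresolved"` together with the
#' tied taxa.
#'
#' @param dist A `taxon_distribution` from [assign_node_taxonomy()].
#' @return List `top_taxon`, `top_weight`, `tied` (character vector),
#'   `distribution` (named numeric).
#' @export
infer_parental_taxon <- function(dist) {
  stopifnot(inherits(dist, "taxon_distribution"))
  p <- dist$dist[dist$root_row, ]
  names(p) <- colnames(dist$dist)
  top <- max(p)
  tied <- names(p)[abs(p - top) < 1e-12]
  list(top_taxon = if (length(tied) > 1) "unresolved" else tied,
       top_weight = unname(top),
       tied = tied,
       distribution = p)
}

#' Summarise donor-assignment stability across the coefficient grid
#'
#' Runs whose trees fail eukaryote monophyly are kept in the table but
#' excluded from the mode and the stability fraction. The modal taxon is
#' the most frequent top taxon among usable runs (ties give
#' `"unresolved"`); stability is its frequency among usable runs.
#'
#' @param per_c Data frame with columns `c`, `euk_monophyletic`
#'   (logical), `top_taxon`, `top_weight` (and any extra columns).
#' @return A `donor_summary` list: `table`, `mode_taxon`, `stability`,
#'   `n_usable`.
#' @export
summarize_donor_stability <- function(per_c) {
  stopifnot(nrow(per_c) >= 1,
            all(c("c", "euk_monophyletic", "top_taxon", "top_weight") %in%
                  names(per_c)))
  usable <- per_c[per_c$euk_monophyletic %in% TRUE, , drop = FALSE]
  if (!nrow(usable)) {
    return(structure(list(table = per_c, mode_taxon = "none",
                          stability = 0, n_usable = 0L),
                     class = "donor_summary"))
  }
  tab <- table(usable$top_taxon)
  top <- names(tab)[tab == max(tab)]
  mode_taxon <- if (length(top) > 1) "unresolved" else top
  stability <- max(tab) / nrow(usable)
  structure(list(table = per_c, mode_taxon = mode_taxon,
                 stability = unname(stability), n_usable = nrow(usable)),
            class = "donor_summary")
}

#' @export
print.donor_summary <- function(x, ...) {
  cat("donor_summary:", nrow(x$table), "datasets,", x$n_usable,
      "usable; mode taxon", x$mode_taxon,
      sprintf("(stability %.2f)\n", x$stability))
  invisible(x)
}

#' Run donor inference across nested datasets
#'
#' For each dataset of the coefficient grid the full homologue tree is
#' restricted to the dataset members (dropping the other leaves), rooted
#' between the domains, checked for eukaryote monophyly, and — when
#' rooting succeeds — the parental prokaryotic node is assigned a taxon
#' distribution. Tree inference itself is external to this package: pass
#' either one tree per dataset (`trees` as a list parallel to the grid)
#' or a single comprehensive tree to be pruned per dataset.
#'
#' @param tree A comprehensive [ape::phylo] over all homologue ids, or
#'   `NULL` if `trees` is given.
#' @param homologs Data frame `id`, `score`, `domain` (see
#'   [generate_nested_datasets()]).
#' @param taxon_map Data frame `id`, `domain`, `taxon`.
#' @param trees Optional list of per-dataset trees (same order as the
#'   grid rows), e.g. re-inferred externally per dataset.
#' @param node_weighting Passed to [assign_node_taxonomy()].
#' @param c_hi,c_lo,step Grid parameters.
#' @return A `donor_summary`; its `table` has one row per grid value with
#'   `c`, `n_members`, `euk_monophyletic`, `support`, `top_taxon`,
#'   `top_weight`.
#' @export
run_donor_pipeline <- function(tree, homologs, taxon_map, trees = NULL,
                               node_weighting = "children",
                               c_hi = 0.99, c_lo = 0.70, step = 0.01) {
  specs <- generate_nested_datasets(homologs, c_hi = c_hi, c_lo = c_lo,
                                    step = step)
  rows <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    ids <- specs$members[[i]]
    tr_i <- if (!is.null(trees)) trees[[i]]
            else ape::keep.tip(tree, intersect(tree$tip.label, ids))
    row <- data.frame(c = specs$c[i], n_members = specs$n_members[i],
                      euk_monophyletic = FALSE, support = NA_real_,
                      top_taxon = NA_character_, top_weight = NA_real_,
                      stringsAsFactors = FALSE)
    rooted <- root_between_domains(tr_i, taxon_map)
    mono <- test_eukaryote_monophyly(rooted)
    row$euk_monophyletic <- isTRUE(mono$monophyletic)
    row$support <- mono$support
    if (rooted$separable) {
      td <- assign_node_taxonomy(rooted, taxon_map,
                                 node_weighting = node_weighting)
      pt <- infer_parental_taxon(td)
      row$top_taxon <- pt$top_taxon
      row$top_weight <- pt$top_weight
    }
    rows[[i]] <- row
  }
  summarize_donor_stability(do.call(rbind, rows))
}
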