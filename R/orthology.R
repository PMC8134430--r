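## Species-overlap orthology over phylome gene trees, pooling of the
## per-seed ortholog pairs into a weighted network, network trimming
## (support filter + gene-fusion splitting by alignment-interval
## Jaccard), orthogroup extraction and phyletic-profile selection.

#' Infer seed-centred ortholog pairs from a gene tree (species overlap)
#'
#' The tree is midpoint-rooted, each internal node is labelled a
#' duplication if the species sets of its child subtrees intersect and a
#' speciation otherwise, and `(seed, x)` is reported for every other leaf
#' `x` whose most recent common ancestor with the seed is a speciation
#' node. This is the reference-species-tree-independent orthology rule
#' used in phylome pipelines.
#'
#' @param tree [ape::phylo] gene tree with a `seed_id` attribute (or pass
#'   `seed_id`).
#' @param species_of Named character vector gene id -> species, covering
#'   all leaves.
#' @param seed_id Seed gene id; defaults to `attr(tree, "seed_id")`.
#' @return Data frame with columns `gene_a` (seed), `gene_b`.
#' @export
infer_ortholog_pairs <- function(tree, species_of, seed_id = attr(tree, "seed_id")) {
  stopifnot(!is.null(seed_id), seed_id %in% tree$tip.label)
  if (any(is.na(species_of[tree$tip.label])))
    stop("species lookup missing for some leaves")
  ntip <- length(tree$tip.label)
  if (ntip < 2) return(data.frame(gene_a = character(), gene_b = character()))
  tr <- tree
  if (!ape::is.rooted(tr) || ntip > 2) {
    if (is.null(tr$edge.length)) tr$edge.length <- rep(1, nrow(tr$edge))
    tr <- phangorn::midpoint(tr)
  }
  nnode <- tr$Nnode
  ## species set per node, postorder
  tr <- ape::reorder.phylo(tr, "postorder")
  spset <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) spset[[i]] <- unname(species_of[tr$tip.label[i]])
  dup <- logical(ntip + nnode)
  kids <- split(tr$edge[, 2], tr$edge[, 1])
  for (nd in unique(tr$edge[, 1])) {
    ch <- kids[[as.character(nd)]]
    sets <- lapply(ch, function(c) spset[[c]])
    inter <- FALSE
    if (length(sets) > 1) {
      for (a in seq_len(length(sets) - 1))
        for (b in (a + 1):length(sets))
          if (length(intersect(sets[[a]], sets[[b]]))) inter <- TRUE
    }
    dup[nd] <- inter
    spset[[nd]] <- unique(unlist(sets))
  }
  seed_tip <- match(seed_id, tr$tip.label)
  others <- setdiff(seq_len(ntip), seed_tip)
  mrca_mat <- ape::mrca(tr)
  ok <- vapply(others, function(x) !dup[mrca_mat[seed_tip, x]], TRUE)
  orth <- tr$tip.label[others[ok]]
  data.frame(gene_a = rep(seed_id, length(orth)), gene_b = orth,
             stringsAsFactors = FALSE)
}

#' Pool per-seed ortholog pairs into an orthology network
#'
#' Edge support counts the phylome entries (seed trees) asserting the
#' unordered pair; because reported pairs always contain their seed, a
#' pair can be asserted at most twice (once from each endpoint's tree).
#'
#' @param pair_sets List of data frames with columns `gene_a`, `gene_b`
#'   (each from one seed tree, `gene_a` the seed).
#' @param nodes Optional data frame `id`, `species` declaring all genes
#'   (so genes with no edges still form singleton orthogroups); defaults
#'   to the genes present in the pairs.
#' @return An `orthology_network`: list with `nodes`, `edges`
#'   (`gene_a < gene_b`, `support`), and `fusion_splits`.
#' @export
assemble_network <- function(pair_sets, nodes = NULL) {
  pairs <- do.call(rbind, pair_sets)
  if (is.null(pairs) || !nrow(pairs)) {
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        support = integer())
  } else {
    a <- pmin(pairs$gene_a, pairs$gene_b)
    b <- pmax(pairs$gene_a, pairs$gene_b)
    ## dedupe within a seed tree, then count seeds per unordered pair
    key <- unique(paste(pairs$gene_a, a, b, sep = "\r"))
    parts <- do.call(rbind, strsplit(key, "\r", fixed = TRUE))
    tab <- table(paste(parts[, 2], parts[, 3], sep = "\r"))
    ab <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
    edges <- data.frame(gene_a = ab[, 1], gene_b = ab[, 2],
                        support = as.integer(tab), stringsAsFactors = FALSE)
    edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  if (is.null(nodes)) {
    ids <- sort(unique(c(edges$gene_a, edges$gene_b)))
    nodes <- data.frame(id = ids, species = rep(NA_character_, length(ids)),
                        stringsAsFactors = FALSE)
  }
  if (anyDuplicated(nodes$id)) stop("duplicate node id")
  missing <- setdiff(c(edges$gene_a, edges$gene_b), nodes$id)
  if (length(missing)) stop("edge endpoint not in nodes: ",
                            paste(missing, collapse = ", "))
  structure(list(nodes = nodes, edges = edges, fusion_splits = list()),
            class = "orthology_network")
}

#' @export
print.orthology_network <- function(x, ...) {
  cat("orthology_network:", nrow(x$nodes), "genes,", nrow(x$edges),
      "edges,", length(x$fusion_splits), "fusion splits\n")
  invisible(x)
}

.interval_jaccard <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]) + 1)
  uni <- (a[2] - a[1] + 1) + (b[2] - b[1] + 1) - inter
  inter / uni
}

#' Trim an orthology network
#'
#' Two successive steps. (1) Support filter: edges asserted by fewer than
#' `min_support` phylomes are dropped. (2) Gene-fusion splitting: for a
#' node whose incident edges align to it over regions that partition into
#' two or more groups with pairwise interval-overlap Jaccard at most
#' `fusion_jaccard_max` (single-linkage grouping on Jaccard >
#' `fusion_jaccard_max`), the node is split into region-restricted
#' sub-nodes (`id#1`, `id#2`, ... ordered by region start) and each edge
#' is reattached to the sub-node whose region contains its alignment-span
#' midpoint. Regions are the 1-based query spans from the hit table; a
#' node with no coordinate data is left intact with a warning. With
#' `min_support = 1` and fusion splitting disabled the network is
#' returned unchanged.
#'
#' @param net An `orthology_network`.
#' @param min_support Minimum edge support kept (>= 1).
#' @param fusion_jaccard_max Jaccard threshold at or below which regions
#'   count as disjoint, or `NULL` to disable fusion handling.
#' @param hits Hit table supplying alignment coordinates (needed when
#'   fusion handling is on).
#' @return The trimmed `orthology_network` (splits recorded in
#'   `fusion_splits`).
#' @export
trim_network <- function(net, min_support = 1, fusion_jaccard_max = NULL,
                         hits = NULL) {
  stopifnot(inherits(net, "orthology_network"), min_support >= 1)
  edges <- net$edges[net$edges$support >= min_support, , drop = FALSE]
  nodes <- net$nodes
  splits <- list()
  if (!is.null(fusion_jaccard_max) && nrow(edges)) {
    if (is.null(hits)) stop("fusion splitting needs a hit table")
    for (g in unique(c(edges$gene_a, edges$gene_b))) {
      idx <- which(edges$gene_a == g | edges$gene_b == g)
      if (length(idx) < 2) next
      partner <- ifelse(edges$gene_a[idx] == g, edges$gene_b[idx],
                        edges$gene_a[idx])
      reg <- t(vapply(partner, function(p) {
        h <- hits[hits$qseqid == g & hits$sseqid == p, , drop = FALSE]
        if (nrow(h)) c(h$qstart[1], h$qend[1])
        else {
          h2 <- hits[hits$qseqid == p & hits$sseqid == g, , drop = FALSE]
          if (nrow(h2)) c(h2$sstart[1], h2$send[1]) else c(NA_real_, NA_real_)
        }
      }, c(0, 0)))
      if (anyNA(reg)) {
        warning("no alignment coordinates for node ", g, "; not split")
        next
      }
      k <- length(idx)
      adj <- matrix(FALSE, k, k)
      for (a in seq_len(k)) for (b in seq_len(k))
        adj[a, b] <- .interval_jaccard(reg[a, ], reg[b, ]) > fusion_jaccard_max
      comp <- .components_bool(adj)
      if (max(comp) < 2) next
      ## order sub-nodes by region start of their group
      starts <- vapply(seq_len(max(comp)), function(c) min(reg[comp == c, 1]), 0)
      ord <- order(starts)
      sub_ids <- character(max(comp))
      sub_regions <- list()
      for (r in seq_along(ord)) {
        c <- ord[r]
        sub_ids[c] <- paste0(g, "#", r)
        sub_regions[[sub_ids[c]]] <- c(min(reg[comp == c, 1]),
                                       max(reg[comp == c, 2]))
      }
      splits[[g]] <- sub_regions
      sp <- nodes$species[match(g, nodes$id)]
      nodes <- nodes[nodes$id != g, , drop = FALSE]
      nodes <- rbind(nodes, data.frame(id = unlist(sub_ids)[order(unlist(sub_ids))],
                                       species = sp, stringsAsFactors = FALSE))
      mid <- (reg[, 1] + reg[, 2]) / 2
      for (e in seq_along(idx)) {
        target <- sub_ids[comp[e]]
        if (edges$gene_a[idx[e]] == g) edges$gene_a[idx[e]] <- target
        else edges$gene_b[idx[e]] <- target
      }
      swap <- edges$gene_a > edges$gene_b
      tmp <- edges$gene_a[swap]
      edges$gene_a[swap] <- edges$gene_b[swap]
      edges$gene_b[swap] <- tmp
    }
  }
  rownames(edges) <- NULL
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges, fusion_splits = splits),
            class = "orthology_network")
}

## connected components of a boolean adjacency matrix (tiny n)
.components_bool <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v]) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

#' Extract orthogroups as connected components
#'
#' @param net A (trimmed) `orthology_network`.
#' @return Data frame with columns `group_id` (`OG1`, `OG2`, ... in order
#'   of each group's smallest gene id), `gene_id`, `species`.
#' @export
extract_orthogroups <- function(net) {
  stopifnot(inherits(net, "orthology_network"))
  if (!nrow(net$nodes))
    return(data.frame(group_id = character(), gene_id = character(),
                      species = character()))
  g <- igraph::graph_from_data_frame(
    net$edges[, c("gene_a", "gene_b"), drop = FALSE],
    directed = FALSE, vertices = net$nodes$id)
  comp <- igraph::components(g)$membership
  ## stable group ids: order components by their smallest member id
  smallest <- tapply(names(comp), comp, min)
  rank <- match(comp, as.integer(names(sort(smallest))))
  d <- data.frame(group_id = paste0("OG", rank),
                  gene_id = names(comp),
                  species = net$nodes$species[match(names(comp), net$nodes$id)],
                  stringsAsFactors = FALSE)
  d <- d[order(as.integer(sub("OG", "", d$group_id)), d$gene_id), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Per-species member-count profile of each orthogroup
#'
#' @param orthogroups Data frame from [extract_orthogroups()].
#' @return Integer matrix, orthogroups x species (counts; presence is
#'   count >= 1, so within-species paralogues are retained).
#' @export
orthogroup_profiles <- function(orthogroups) {
  if (!nrow(orthogroups))
    return(matrix(integer(), 0, 0))
  t(unclass(table(orthogroups$species, orthogroups$group_id)))
}

#' Define a species panel
#'
#' @param positive Species expected to carry the marker pathway.
#' @param negative Species confidently lacking it; membership of a
#'   candidate family in any of these disqualifies it.
#' @param exempt Species with incomplete data (EST-only surveys,
#'   single-cell transcriptomes, partial pathway) whose absence calls are
#'   untrusted: ignored by both the positive and the negative test.
#' @param required_all Subset of `positive` that a confirmed family must
#'   cover.
#' @return A `species_panel` list.
#' @export
species_panel <- function(positive, negative, exempt = character(),
                          required_all = positive) {
  if (length(intersect(positive, negative)) ||
      length(intersect(positive, exempt)) ||
      length(intersect(negative, exempt)))
    stop("positive/negative/exempt lists must be pairwise disjoint")
  if (!all(required_all %in% positive))
    stop("required_all must be a subset of positive")
  structure(list(positive = positive, negative = negative, exempt = exempt,
                 required_all = required_all), class = "species_panel")
}

#' Select orthogroups matching the target phyletic profile
#'
#' Keeps orthogroups with members in at least `min_positive` positive
#' species and none in any negative species. Exempt species are ignored
#' by both tests. Adding a species to `exempt` can therefore never shrink
#' the candidate set, and adding one to `negative` can never grow it.
#'
#' @param orthogroups Data frame from [extract_orthogroups()].
#' @param panel A [species_panel()].
#' @param min_positive Minimum number of distinct positive species.
#' @param declared_absent Species known to be absent from the input
#'   proteomes (profile species outside the panel and this list raise a
#'   configuration error).
#' @return Data frame `group_id`, `positive_count`, `negative_count`,
#'   `candidate` (logical), candidates first.
#' @export
match_phyletic_profile <- function(orthogroups, panel, min_positive = 2,
                                   declared_absent = character()) {
  stopifnot(inherits(panel, "species_panel"))
  known <- c(panel$positive, panel$negative, panel$exempt, declared_absent)
  extra <- setdiff(unique(orthogroups$species), known)
  if (length(extra))
    stop("species in profiles but not in panel or declared_absent: ",
         paste(extra, collapse = ", "))
  groups <- unique(orthogroups$group_id)
  pos <- vapply(groups, function(g) {
    length(intersect(unique(orthogroups$species[orthogroups$group_id == g]),
                     panel$positive))
  }, 0L)
  neg <- vapply(groups, function(g) {
    length(intersect(unique(orthogroups$species[orthogroups$group_id == g]),
                     panel$negative))
  }, 0L)
  d <- data.frame(group_id = groups, positive_count = pos,
                  negative_count = neg,
                  candidate = pos >= min_positive & neg == 0L,
                  stringsAsFactors = FALSE)
  d <- d[order(-d$candidate, d$group_id), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Confirm full presence across the required species set
#'
#' A candidate orthogroup is a bona fide co-occurring family only if,
#' after adding any targeted-research rescue hits, it has a
#' representative in every species of `required_all`. Rescue hits model
#' the manual re-searches that recover short genes missed by automated
#' annotation; they are ingested as evidence, not computed here.
#'
#' @param orthogroups Membership data frame (only candidate groups are
#'   examined).
#' @param candidates Data frame from [match_phyletic_profile()].
#' @param required_all Character vector of species that must all be
#'   covered.
#' @param rescue_hits Optional data frame `group_id`, `species`,
#'   `gene_id` of additional members found by targeted searches.
#' @return Data frame `group_id`, `covered`, `rescued_species`,
#'   `bona_fide`.
#' @export
confirm_full_presence <- function(orthogroups, candidates, required_all,
                                  rescue_hits = NULL) {
  cand <- candidates$group_id[candidates$candidate]
  if (!is.null(rescue_hits) && nrow(rescue_hits)) {
    unknown <- setdiff(rescue_hits$group_id, candidates$group_id)
    if (length(unknown))
      stop("rescue hit references unknown group: ",
           paste(unknown, collapse = ", "))
  }
  out <- lapply(cand, function(g) {
    sp <- unique(orthogroups$species[orthogroups$group_id == g])
    rescued <- character()
    if (!is.null(rescue_hits)) {
      r <- rescue_hits[rescue_hits$group_id == g, , drop = FALSE]
      rescued <- setdiff(unique(r$species), sp)
      sp <- union(sp, r$species)
    }
    data.frame(group_id = g,
               covered = sum(required_all %in% sp),
               rescued_species = paste(sort(rescued), collapse = ","),
               bona_fide = all(required_all %in% sp),
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, out)
  if (is.null(d))
    d <- data.frame(group_id = character(), covered = integer(),
                    rescued_species = character(), bona_fide = logical())
  d
}
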