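## Distance gene trees for phylome construction: Kimura-corrected
## identity distances from the hit table, and a deterministic
## neighbour-joining implementation with a lexicographic tie-break so
## that repeated runs yield byte-identical trees.

#' Kimura-corrected protein distance from fractional identity
#'
#' `d = -ln(1 - D - 0.2 D^2)` with `D = 1 - identity`. Divergences at or
#' beyond the domain of the correction (D >= ~0.854) are capped at
#' `cap`.
#'
#' @param identity Fractional identity in `[0, 1]`.
#' @param cap Distance assigned to saturated pairs.
#' @return Distance(s) >= 0.
#' @export
kimura_distance <- function(identity, cap = 10) {
  d <- 1 - identity
  arg <- 1 - d - 0.2 * d^2
  out <- ifelse(arg <= 0, cap, -log(arg))
  pmin(pmax(out, 0), cap)
}

#' Pairwise distance matrix from a hit table
#'
#' Identity of a pair is the mean `pident` over the (up to two) query
#' directions in which it was reported; pairs with no reported hit get
#' the saturation cap. Diagonal is zero.
#'
#' @param ids Gene ids (matrix order).
#' @param hits Hit table (outfmt-6 columns).
#' @param cap Distance for unrelated pairs.
#' @return Symmetric numeric matrix with dimnames `ids`.
#' @export
hits_distance_matrix <- function(ids, hits, cap = 10) {
  n <- length(ids)
  pid_sum <- matrix(0, n, n, dimnames = list(ids, ids))
  pid_n <- matrix(0L, n, n)
  h <- hits[hits$qseqid %in% ids & hits$sseqid %in% ids &
              hits$qseqid != hits$sseqid, , drop = FALSE]
  if (nrow(h)) {
    i <- match(h$qseqid, ids); j <- match(h$sseqid, ids)
    for (k in seq_len(nrow(h))) {
      pid_sum[i[k], j[k]] <- pid_sum[i[k], j[k]] + h$pident[k]
      pid_n[i[k], j[k]] <- pid_n[i[k], j[k]] + 1L
    }
  }
  tot <- pid_sum + t(pid_sum)
  cnt <- pid_n + t(pid_n)
  d <- matrix(cap, n, n, dimnames = list(ids, ids))
  seen <- cnt > 0
  d[seen] <- kimura_distance(tot[seen] / cnt[seen] / 100, cap = cap)
  diag(d) <- 0
  d
}

#' Deterministic neighbour-joining tree
#'
#' Standard neighbour joining (Saitou-Nei, Studier-Keppler Q matrix) with
#' one addition: when several pairs minimise Q, the pair whose labels
#' (the lexicographically smallest leaf id under each cluster) sort first
#' is joined. Negative branch-length estimates are clamped to zero. The
#' result is the unrooted topology as an [ape::phylo] with a
#' trifurcating root.
#'
#' @param d Symmetric distance matrix with unique dimnames.
#' @return An [ape::phylo].
#' @export
nj_tree <- function(d) {
  labs <- rownames(d)
  stopifnot(!is.null(labs), !anyDuplicated(labs), nrow(d) >= 2)
  n <- nrow(d)
  if (n == 2) {
    bl <- d[1, 2] / 2
    return(ape::read.tree(text = sprintf("(%s:%g,%s:%g);",
                                         labs[1], bl, labs[2], bl)))
  }
  ## working state: newick fragments, representative label = smallest leaf
  frag <- labs
  rep_lab <- labs
  dm <- d
  while (nrow(dm) > 3) {
    m <- nrow(dm)
    r <- rowSums(dm)
    q <- (m - 2) * dm - outer(r, r, `+`)
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- paste(pmin(rep_lab[cand[, 1]], rep_lab[cand[, 2]]),
                 pmax(rep_lab[cand[, 1]], rep_lab[cand[, 2]]))
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    bi <- max(0, dm[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2)))
    bj <- max(0, dm[i, j] - bi)
    newfrag <- sprintf("(%s:%g,%s:%g)", frag[i], bi, frag[j], bj)
    newrep <- min(rep_lab[i], rep_lab[j])
    dnew <- (dm[i, ] + dm[j, ] - dm[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    dm2 <- rbind(cbind(dm[keep, keep, drop = FALSE], dnew[keep]),
                 c(dnew[keep], 0))
    frag <- c(frag[keep], newfrag)
    rep_lab <- c(rep_lab[keep], newrep)
    dm <- dm2
  }
  ## terminal 3-star
  b1 <- max(0, (dm[1, 2] + dm[1, 3] - dm[2, 3]) / 2)
  b2 <- max(0, (dm[1, 2] + dm[2, 3] - dm[1, 3]) / 2)
  b3 <- max(0, (dm[1, 3] + dm[2, 3] - dm[1, 2]) / 2)
  txt <- sprintf("(%s:%g,%s:%g,%s:%g);", frag[1], b1, frag[2], b2, frag[3], b3)
  ape::read.tree(text = txt)
}

#' Build a phylome gene tree for one seed gene
#'
#' Takes the seed's best `max_homologs` non-self hits, computes pairwise
#' Kimura-corrected identity distances from the hit table and returns the
#' neighbour-joining tree over seed + homologues. Deterministic given its
#' inputs.
#'
#' @param seed_id Seed gene id.
#' @param hits Hit table covering the seed's searches.
#' @param max_homologs Maximum number of homologues retained.
#' @return An [ape::phylo] with attribute `seed_id`, or `NULL` when fewer
#'   than two sequences remain (the skip signal, not an error).
#' @export
build_gene_tree <- function(seed_id, hits, max_homologs = 15) {
  h <- hits[hits$qseqid == seed_id & hits$sseqid != seed_id, , drop = FALSE]
  if (!nrow(h)) return(NULL)
  h <- h[order(-h$bitscore, h$sseqid), , drop = FALSE]
  ids <- c(seed_id, head(unique(h$sseqid), max_homologs))
  if (length(ids) < 2) return(NULL)
  d <- hits_distance_matrix(sort(ids), hits)
  tr <- nj_tree(d)
  attr(tr, "seed_id") <- seed_id
  tr
}
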