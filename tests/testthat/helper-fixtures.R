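# Small in-code fixtures shared across test files.

# intensity table built from a named list fraction -> matrix-free spec:
# m is proteins x (3 fractions x n_reps) numeric with NA for missing
make_tab <- function(m, fractions = c("Opt1015", "Opt1520", "Opt2030"),
                     n_reps = ncol(m) / length(fractions)) {
  colnames(m) <- paste0(rep(fractions, each = n_reps), "_r",
                        rep(seq_len(n_reps), length(fractions)))
  if (is.null(rownames(m))) rownames(m) <- paste0("p", seq_len(nrow(m)))
  intensity_table(m)
}

# taxon map for leaves named Euk_*/<Phylum>_<i>
taxmap_from_labels <- function(labels) {
  data.frame(
    id = labels,
    domain = ifelse(grepl("^E", labels), "eukaryote", "prokaryote"),
    taxon = ifelse(grepl("^E", labels), "", sub("_[0-9]+$", "", labels)),
    stringsAsFactors = FALSE)
}

# brute-force partition of a graph into connected components by boolean
# matrix closure; returns canonical list of sorted member vectors
closure_partition <- function(ids, edges) {
  n <- length(ids)
  A <- diag(TRUE, n)
  dimnames(A) <- list(ids, ids)
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    A[edges$gene_a[k], edges$gene_b[k]] <- TRUE
    A[edges$gene_b[k], edges$gene_a[k]] <- TRUE
  }
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A)) break
    A <- A2
  }
  groups <- unique(apply(A, 1, function(r) paste(sort(ids[r]), collapse = ",")))
  unname(sort(groups))
}

# canonical partition from an extract_orthogroups result
og_partition <- function(og) {
  unname(sort(vapply(split(og$gene_id, og$group_id),
                     function(g) paste(sort(g), collapse = ","), "")))
}

edges_df <- function(a, b) {
  data.frame(gene_a = a, gene_b = b, support = rep(1L, length(a)),
             stringsAsFactors = FALSE)
}

# random edge set over n nodes
random_graph <- function(n, p = 0.15) {
  ids <- paste0("g", seq_len(n))
  pairs <- t(combn(ids, 2))
  keep <- runif(nrow(pairs)) < p
  list(ids = ids, edges = edges_df(pairs[keep, 1], pairs[keep, 2]))
}

network_from <- function(ids, edges, species = NA_character_) {
  assemble_network(list(), nodes = data.frame(id = ids, species = species,
                                              stringsAsFactors = FALSE)) -> net
  net$edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(net$edges) <- NULL
  net
}
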