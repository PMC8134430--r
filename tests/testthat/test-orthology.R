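species_lookup <- function(...) {
  x <- c(...)
  setNames(sub("^.*_", "", x), x)
}

test_that("species-overlap orthology follows the duplication rule", {
  sp <- species_lookup("seed_sp1", "b_sp2", "c_sp3", "a2_sp1")

  # no duplications: both leaves are orthologs of the seed
  tr <- ape::read.tree(text = "((seed_sp1:1,b_sp2:1):1,c_sp3:2);")
  p <- infer_ortholog_pairs(tr, sp, seed_id = "seed_sp1")
  expect_setequal(p$gene_b, c("b_sp2", "c_sp3"))

  # node joining two sp1 genes is a duplication: a2 is a paralogue,
  # b (MRCA = speciation root) remains an ortholog
  tr <- ape::read.tree(text = "((seed_sp1:1,a2_sp1:1):1,b_sp2:2);")
  p <- infer_ortholog_pairs(tr, sp, seed_id = "seed_sp1")
  expect_equal(p$gene_b, "b_sp2")

  # all leaves one species: no orthologs at all
  sp1 <- setNames(rep("sp1", 3), c("seed_sp1", "x_sp1", "y_sp1"))
  tr <- ape::read.tree(text = "((seed_sp1:1,x_sp1:1):1,y_sp1:2);")
  p <- infer_ortholog_pairs(tr, sp1, seed_id = "seed_sp1")
  expect_equal(nrow(p), 0)
})

test_that("network assembly counts phylome support per unordered pair", {
  # both endpoint phylomes assert (a, b); only a's asserts (a, c)
  sets <- list(data.frame(gene_a = "a", gene_b = c("b", "c")),
               data.frame(gene_a = "b", gene_b = "a"))
  net <- assemble_network(sets)
  e <- net$edges
  expect_equal(e$support[e$gene_a == "a" & e$gene_b == "b"], 2L)
  expect_equal(e$support[e$gene_a == "a" & e$gene_b == "c"], 1L)

  # duplicate assertion within one phylome counts once
  net2 <- assemble_network(list(data.frame(gene_a = "a", gene_b = c("b", "b"))))
  expect_equal(net2$edges$support, 1L)

  empty <- assemble_network(list())
  expect_equal(nrow(empty$edges), 0)
  expect_equal(nrow(empty$nodes), 0)
})

test_that("trimming drops weak edges and is the identity when disabled", {
  sets <- list(data.frame(gene_a = "a", gene_b = c("b", "c")),
               data.frame(gene_a = "b", gene_b = "a"))
  net <- assemble_network(sets)
  t1 <- trim_network(net, min_support = 2)
  expect_equal(nrow(t1$edges), 1)
  expect_equal(t1$edges$gene_a, "a")
  expect_equal(t1$edges$gene_b, "b")
  # support filter at 1, fusion disabled: unchanged
  t0 <- trim_network(net, min_support = 1)
  expect_equal(t0$edges, net$edges)
  expect_equal(t0$nodes, net$nodes)
  # empty network passes through
  expect_equal(nrow(trim_network(assemble_network(list()))$edges), 0)
})

test_that("gene fusions split into region-restricted sub-nodes", {
  # g aligns to n1 over 1-100 and to n2 over 150-250: interval Jaccard 0,
  # so g splits; midpoints 50 and 200 land in g#1 and g#2
  sets <- list(data.frame(gene_a = "g", gene_b = c("n1", "n2")))
  net <- assemble_network(sets)
  hits <- data.frame(
    qseqid = c("g", "g"), sseqid = c("n1", "n2"),
    pident = 90, length = c(100, 101),
    qstart = c(1, 150), qend = c(100, 250),
    sstart = 1, send = c(100, 101), evalue = 1e-30, bitscore = 200)
  tr <- trim_network(net, min_support = 1, fusion_jaccard_max = 0, hits = hits)
  expect_setequal(tr$nodes$id[grepl("^g#", tr$nodes$id)], c("g#1", "g#2"))
  expect_equal(tr$fusion_splits$g[["g#1"]], c(1, 100))
  expect_equal(tr$fusion_splits$g[["g#2"]], c(150, 250))
  e <- tr$edges
  expect_true(any(e$gene_a == "g#1" & e$gene_b == "n1"))
  expect_true(any(e$gene_a == "g#2" & e$gene_b == "n2"))

  # a node with overlapping regions is not split
  hits2 <- hits; hits2$qstart <- c(1, 50); hits2$qend <- c(100, 150)
  tr2 <- trim_network(net, min_support = 1, fusion_jaccard_max = 0.1,
                      hits = hits2)
  expect_false(any(grepl("#", tr2$nodes$id)))

  # missing coordinates: warn, leave intact
  expect_warning(
    trim_network(net, min_support = 1, fusion_jaccard_max = 0,
                 hits = hits[1, , drop = FALSE]),
    "no alignment coordinates")
})

test_that("orthogroups equal the transitive-closure partition", {
  # hand cases
  net <- assemble_network(list(data.frame(gene_a = c("a", "b"),
                                          gene_b = c("b", "c"))))
  expect_equal(og_partition(extract_orthogroups(net)), "a,b,c")
  net2 <- assemble_network(list(data.frame(gene_a = c("a", "c"),
                                           gene_b = c("b", "d"))))
  expect_equal(og_partition(extract_orthogroups(net2)), c("a,b", "c,d"))

  # exhaustive oracle comparison on all graphs with up to 5 nodes
  for (n in 2:5) {
    ids <- paste0("g", seq_len(n))
    pairs <- t(combn(ids, 2))
    for (mask in 0:(2^nrow(pairs) - 1)) {
      sel <- bitwAnd(mask, 2^(seq_len(nrow(pairs)) - 1)) > 0
      edges <- edges_df(pairs[sel, 1], pairs[sel, 2])
      net <- network_from(ids, edges)
      expect_identical(og_partition(extract_orthogroups(net)),
                       closure_partition(ids, edges))
    }
  }

  # random larger graphs
  set.seed(41)
  for (i in 1:50) {
    g <- random_graph(sample(6:20, 1))
    net <- network_from(g$ids, g$edges)
    expect_identical(og_partition(extract_orthogroups(net)),
                     closure_partition(g$ids, g$edges))
  }
})

test_that("profile matching applies the positive/negative/exempt rules", {
  panel <- species_panel(positive = c("Ngruberi", "Agodoyi", "Mjakobiformis"),
                         negative = c("Hsapiens", "Scerevisiae"),
                         exempt = "Percolomonas")
  og <- data.frame(
    group_id = c("OG1", "OG1", "OG2", "OG3", "OG3", "OG3", "OG3",
                 "OG4", "OG4", "OG4"),
    gene_id = paste0("g", 1:10),
    species = c("Ngruberi", "Agodoyi",          # OG1: two positives
                "Ngruberi",                     # OG2: one positive
                "Ngruberi", "Agodoyi", "Mjakobiformis", "Hsapiens",  # OG3
                "Ngruberi", "Agodoyi", "Percolomonas"),  # OG4: exempt ignored
    stringsAsFactors = FALSE)
  res <- match_phyletic_profile(og, panel)
  expect_true(res$candidate[res$group_id == "OG1"])
  expect_false(res$candidate[res$group_id == "OG2"])
  expect_false(res$candidate[res$group_id == "OG3"])
  expect_true(res$candidate[res$group_id == "OG4"])

  # the same leaky group qualifies once the offending species is exempt
  panel2 <- species_panel(positive = panel$positive,
                          negative = "Scerevisiae",
                          exempt = c("Percolomonas", "Hsapiens"))
  res2 <- match_phyletic_profile(og, panel2)
  expect_true(res2$candidate[res2$group_id == "OG3"])

  # unknown species must be declared
  og_bad <- rbind(og, data.frame(group_id = "OG5", gene_id = "g11",
                                 species = "Unknownia"))
  expect_error(match_phyletic_profile(og_bad, panel), "Unknownia")
  expect_silent(match_phyletic_profile(og_bad, panel,
                                       declared_absent = "Unknownia"))
})

test_that("profile matching is monotone in the panel lists", {
  set.seed(43)
  all_sp <- paste0("S", 1:8)
  for (i in 1:25) {
    ng <- sample(3:6, 1)
    og <- do.call(rbind, lapply(seq_len(ng), function(g) {
      sp <- sample(all_sp, sample(1:5, 1))
      data.frame(group_id = paste0("OG", g),
                 gene_id = paste0("OG", g, "_", sp), species = sp,
                 stringsAsFactors = FALSE)
    }))
    pos <- sample(all_sp, 3)
    rest <- setdiff(all_sp, pos)
    neg <- sample(rest, 3)
    ex <- setdiff(rest, neg)
    base <- species_panel(pos, neg, ex)
    got <- function(p) {
      r <- match_phyletic_profile(og, p)
      sort(r$group_id[r$candidate])
    }
    # moving a species from negative to exempt can only grow the set
    wider <- species_panel(pos, neg[-1], c(ex, neg[1]))
    expect_true(all(got(base) %in% got(wider)))
    # moving a species from exempt to negative can only shrink it
    narrower <- species_panel(pos, c(neg, ex[1]), ex[-1])
    expect_true(all(got(narrower) %in% got(base)))
  }
})

test_that("full-presence confirmation honours rescue evidence", {
  req <- paste0("S", 1:4)
  og <- data.frame(
    group_id = c(rep("OG1", 4), rep("OG2", 3)),
    gene_id = paste0("g", 1:7),
    species = c(req, req[1:3]),
    stringsAsFactors = FALSE)
  cand <- data.frame(group_id = c("OG1", "OG2"), positive_count = c(4, 3),
                     negative_count = 0, candidate = TRUE)
  res <- confirm_full_presence(og, cand, req)
  expect_true(res$bona_fide[res$group_id == "OG1"])
  expect_false(res$bona_fide[res$group_id == "OG2"])

  rescue <- data.frame(group_id = "OG2", species = "S4", gene_id = "gX")
  res2 <- confirm_full_presence(og, cand, req, rescue_hits = rescue)
  expect_true(res2$bona_fide[res2$group_id == "OG2"])
  expect_equal(res2$rescued_species[res2$group_id == "OG2"], "S4")

  bad <- data.frame(group_id = "OG9", species = "S4", gene_id = "gX")
  expect_error(confirm_full_presence(og, cand, req, rescue_hits = bad),
               "OG9")
})

test_that("species panels enforce disjointness and required subsets", {
  expect_error(species_panel(c("a", "b"), c("b")), "disjoint")
  expect_error(species_panel("a", "b", required_all = "c"), "subset")
  p <- species_panel(c("a", "b"), "c", required_all = "a")
  expect_equal(p$required_all, "a")
})
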