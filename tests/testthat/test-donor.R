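test_that("nested datasets follow the cutoff formula on the coefficient grid", {
  hom <- data.frame(id = c("E1", "P1", "P2", "P3"),
                    score = c(500, 200, 150, 120),
                    domain = c("eukaryote", rep("prokaryote", 3)))
  specs <- generate_nested_datasets(hom)
  expect_equal(nrow(specs), 30)
  expect_equal(specs$c, round(seq(0.99, 0.70, by = -0.01), 2))
  # cutoff = c * best prokaryotic score (the eukaryote score is ignored)
  expect_equal(specs$cutoff[specs$c == 0.70], 0.70 * 200)

  # membership: prok scores {100, 90, 60} at c = 0.85 keep {100, 90}
  hom2 <- data.frame(id = c("E1", "Pa", "Pb", "Pc"),
                     score = c(400, 100, 90, 60),
                     domain = c("eukaryote", rep("prokaryote", 3)))
  specs2 <- generate_nested_datasets(hom2, c_hi = 0.85, c_lo = 0.85)
  expect_setequal(specs2$members[[1]], c("E1", "Pa", "Pb"))

  expect_error(generate_nested_datasets(
    data.frame(id = "E1", score = 1, domain = "eukaryote")),
    "no prokaryotic")
})

test_that("dataset membership is nested and non-increasing in c", {
  set.seed(51)
  for (i in 1:50) {
    np <- sample(5:40, 1)
    hom <- data.frame(
      id = c(paste0("E", 1:3), paste0("P", seq_len(np))),
      score = c(runif(3, 200, 400), runif(np, 10, 310)),
      domain = c(rep("eukaryote", 3), rep("prokaryote", np)))
    specs <- generate_nested_datasets(hom)
    sizes <- specs$n_members
    # grid is ordered from high c to low c: sizes must not decrease
    expect_true(all(diff(sizes) >= 0))
    for (k in seq_len(nrow(specs) - 1))
      expect_true(all(specs$members[[k]] %in% specs$members[[k + 1]]))
    # eukaryotes always present
    expect_true(all(vapply(specs$members,
                           function(m) all(paste0("E", 1:3) %in% m), TRUE)))
  }
})

test_that("rooting between domains handles clean, pendant and tangled trees", {
  tm <- taxmap_from_labels(c("E1", "E2", "P1_a", "P2_a"))

  tr <- ape::read.tree(text = "((E1:1,E2:1):1,(P1_a:1,P2_a:1):1);")
  r <- root_between_domains(tr, tm)
  expect_true(r$separable)
  expect_true(ape::is.rooted(r$tree))
  euk_side <- ape::extract.clade(
    r$tree, ape::getMRCA(r$tree, c("E1", "E2")))$tip.label
  expect_setequal(euk_side, c("E1", "E2"))
  expect_setequal(r$tree$tip.label, tr$tip.label)

  # single eukaryotic leaf roots on its pendant edge
  tm1 <- taxmap_from_labels(c("E1", "P1_a", "P2_a", "P3_b"))
  tr1 <- ape::read.tree(text = "((E1:1,P1_a:1):1,(P2_a:1,P3_b:1):1);")
  r1 <- root_between_domains(tr1, tm1)
  expect_true(r1$separable)
  rootn <- length(r1$tree$tip.label) + 1L
  kids <- r1$tree$edge[r1$tree$edge[, 1] == rootn, 2]
  expect_true(match("E1", r1$tree$tip.label) %in% kids)

  # interleaved domains cannot be separated
  tm2 <- taxmap_from_labels(c("E1", "E2", "P1_a", "P2_a"))
  tr2 <- ape::read.tree(text = "((E1:1,P1_a:1):1,(E2:1,P2_a:1):1);")
  r2 <- root_between_domains(tr2, tm2)
  expect_false(r2$separable)
  expect_true(length(r2$conflicting) >= 1)
  expect_true(all(r2$conflicting %in% c("P1_a", "P2_a")))
})

test_that("the separating-edge support label is carried through rooting", {
  tm <- taxmap_from_labels(c("E1", "E2", "P1_a", "P2_a"))
  tr <- ape::read.tree(text = "((E1:1,E2:1)98:1,(P1_a:1,P2_a:1)77:1);")
  r <- root_between_domains(tr, tm)
  expect_equal(r$euk_clade_support, 98)
})

test_that("monophyly verdicts combine rooting success and support", {
  tm <- taxmap_from_labels(c("E1", "E2", "P1_a", "P2_a"))
  tr <- ape::read.tree(text = "((E1:1,E2:1)98:1,(P1_a:1,P2_a:1)77:1);")
  r <- root_between_domains(tr, tm)
  expect_equal(test_eukaryote_monophyly(r),
               list(monophyletic = TRUE, support = 98))
  expect_equal(test_eukaryote_monophyly(r, min_support = 95)$monophyletic, TRUE)
  expect_equal(test_eukaryote_monophyly(r, min_support = 99)$monophyletic, FALSE)

  # no support label + a threshold -> indeterminate
  tr0 <- ape::read.tree(text = "((E1:1,E2:1):1,(P1_a:1,P2_a:1):1);")
  r0 <- root_between_domains(tr0, tm)
  expect_true(is.na(test_eukaryote_monophyly(r0, min_support = 95)$monophyletic))

  tr2 <- ape::read.tree(text = "((E1:1,P1_a:1):1,(E2:1,P2_a:1):1);")
  r2 <- root_between_domains(tr2, tm)
  expect_equal(test_eukaryote_monophyly(r2)$monophyletic, FALSE)
})

test_that("a homogeneous prokaryotic subtree gives a certain assignment", {
  tm <- data.frame(id = c("E1", "P1", "P2"),
                   domain = c("eukaryote", "prokaryote", "prokaryote"),
                   taxon = c("", "alpha", "alpha"))
  tr <- ape::read.tree(text = "(E1:3,(P1:1,P2:1):1);")
  td <- assign_node_taxonomy(root_between_domains(tr, tm), tm)
  pt <- infer_parental_taxon(td)
  expect_equal(pt$top_taxon, "alpha")
  expect_equal(pt$top_weight, 1)
})

test_that("children-mean taxonomy matches hand recursion, leaf-mean its contrast", {
  # deepest prokaryotic node has children {A: 1} and {A: 0.5, B: 0.5}
  tm <- data.frame(id = c("E1", "p1", "p2", "p3"),
                   domain = c("eukaryote", rep("prokaryote", 3)),
                   taxon = c("", "A", "A", "B"))
  tr <- ape::read.tree(text = "(E1:3,(p1:1,(p2:1,p3:1):1):1);")
  r <- root_between_domains(tr, tm)
  td <- assign_node_taxonomy(r, tm)
  pt <- infer_parental_taxon(td)
  expect_equal(pt$distribution, c(A = 0.75, B = 0.25))
  expect_equal(pt$top_taxon, "A")

  # prok subtree (P_alpha, (P_beta, P_beta)): children-mean 0.5/0.5
  # (a tie -> unresolved), leaf-mean 1/3 vs 2/3
  tm2 <- data.frame(id = c("E1", "p1", "p2", "p3"),
                    domain = c("eukaryote", rep("prokaryote", 3)),
                    taxon = c("", "alpha", "beta", "beta"))
  r2 <- root_between_domains(tr, tm2)
  ptc <- infer_parental_taxon(assign_node_taxonomy(r2, tm2))
  expect_equal(ptc$distribution, c(alpha = 0.5, beta = 0.5))
  expect_equal(ptc$top_taxon, "unresolved")
  expect_setequal(ptc$tied, c("alpha", "beta"))
  ptl <- infer_parental_taxon(assign_node_taxonomy(r2, tm2,
                                                   node_weighting = "leaves"))
  expect_equal(ptl$distribution, c(alpha = 1/3, beta = 2/3))
  expect_equal(ptl$top_taxon, "beta")

  # three-level tree, worked by hand:
  # prok subtree (((a1,b1),(b2,b3)),c1) under children-mean:
  #   (a1,b1) = {a .5, b .5}; (b2,b3) = {b 1}; their parent = {a .25, b .75};
  #   deepest = mean with {c 1} = {a .125, b .375, c .5}
  tm3 <- data.frame(
    id = c("E1", "a1", "b1", "b2", "b3", "c1"),
    domain = c("eukaryote", rep("prokaryote", 5)),
    taxon = c("", "A", "B", "B", "B", "C"))
  tr3 <- ape::read.tree(
    text = "(E1:5,(((a1:1,b1:1):1,(b2:1,b3:1):1):1,c1:2):1);")
  r3 <- root_between_domains(tr3, tm3)
  pt3 <- infer_parental_taxon(assign_node_taxonomy(r3, tm3))
  expect_equal(pt3$distribution, c(A = 0.125, B = 0.375, C = 0.5))
  # leaf-mean contrast: {a 1/5, b 3/5, c 1/5}
  pt3l <- infer_parental_taxon(assign_node_taxonomy(r3, tm3,
                                                    node_weighting = "leaves"))
  expect_equal(pt3l$distribution, c(A = 0.2, B = 0.6, C = 0.2))

  # a leaf without taxon is an error naming the leaf
  tm_bad <- tm3; tm_bad$taxon[2] <- ""
  expect_error(assign_node_taxonomy(r3, tm_bad), "a1")
})

test_that("taxon distributions sum to one at every node of random trees", {
  for (s in 1:20) {
    sim <- simulate_donor_tree(hgt_scenario(seed = s))
    r <- root_between_domains(sim$tree, sim$taxon_map)
    expect_true(r$separable)
    for (w in c("children", "leaves")) {
      td <- assign_node_taxonomy(r, sim$taxon_map, node_weighting = w)
      expect_equal(unname(rowSums(td$dist)), rep(1, nrow(td$dist)),
                   tolerance = 1e-9)
    }
    # rooting never changes the leaf set, and unrooting the result
    # restores the original splits
    expect_setequal(r$tree$tip.label, sim$tree$tip.label)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(r$tree), sim$tree)), 0)
  }
})

test_that("stability summaries count modes among usable runs only", {
  tab <- data.frame(c = c(0.99, 0.98, 0.97, 0.96),
                    euk_monophyletic = c(TRUE, TRUE, TRUE, FALSE),
                    top_taxon = c("X", "X", "Y", "Z"),
                    top_weight = c(0.9, 0.8, 0.6, 0.99))
  s <- summarize_donor_stability(tab)
  expect_equal(s$mode_taxon, "X")
  expect_equal(s$stability, 2 / 3)
  expect_equal(s$n_usable, 3L)
  expect_equal(nrow(s$table), 4)  # non-usable rows retained

  all_x <- data.frame(c = seq(0.99, 0.70, by = -0.01),
                      euk_monophyletic = TRUE,
                      top_taxon = "X", top_weight = 1)
  expect_equal(summarize_donor_stability(all_x)$stability, 1)

  none <- data.frame(c = 0.99, euk_monophyletic = FALSE,
                     top_taxon = NA_character_, top_weight = NA_real_)
  s0 <- summarize_donor_stability(none)
  expect_equal(s0$mode_taxon, "none")
  expect_equal(s0$stability, 0)

  tie <- data.frame(c = c(0.99, 0.98), euk_monophyletic = TRUE,
                    top_taxon = c("X", "Y"), top_weight = 0.9)
  expect_equal(summarize_donor_stability(tie)$mode_taxon, "unresolved")
})

test_that("the donor pipeline summarises a simulated family end to end", {
  sim <- simulate_donor_tree(hgt_scenario(seed = 42))
  s <- run_donor_pipeline(sim$tree, sim$homologs, sim$taxon_map)
  expect_s3_class(s, "donor_summary")
  expect_equal(nrow(s$table), 30)
  expect_equal(s$mode_taxon, sim$donor)
  expect_true(s$stability >= 0.9)
  # per-dataset sizes respect nestedness
  expect_true(all(diff(s$table$n_members) >= 0))
})
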