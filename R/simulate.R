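## Planted-truth simulators for the three analyses. Each generator is a
## pure function of its scenario (seed included): the same scenario
## yields byte-identical artifacts, and every artifact comes with a
## truth table so tests never infer the planted answer from names or
## ordering.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

.random_protein <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(AA20, len, replace = TRUE), collapse = ""), "")
}

.mutate_protein <- function(seq, p_sub) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- runif(length(chars)) < p_sub
  if (any(hit))
    chars[hit] <- vapply(which(hit), function(i)
      sample(setdiff(AA20, chars[i]), 1), "")
  paste(chars, collapse = "")
}

#' Scenario for planted phyletic-profile simulations
#'
#' The default panel mirrors a discovery setting with eight species that
#' carry the marker pathway (all of them required for confirmation),
#' eight that confidently lack it, and three with incomplete data that
#' are exempt from negative calls. Families are planted on a star
#' phylogeny: one ancestor per family, mutated independently into each
#' member species; decoys are unrelated random sequences. 10%
#' substitution per branch keeps family members ~80% identical, far
#' above the detection floor while clearly non-identical.
#'
#' @param panel A [species_panel()].
#' @param families Named list: family name -> character vector of member
#'   species (repeat a species for within-species paralogues).
#' @param n_decoys Number of unrelated decoy genes scattered uniformly
#'   over the panel species.
#' @param seq_len Protein length.
#' @param p_sub Per-branch substitution probability in `[0, 0.95]`.
#' @param seed Integer seed.
#' @return A `profile_scenario` list.
#' @export
profile_scenario <- function(panel = default_profile_panel(),
                             families = default_profile_families(panel),
                             n_decoys = 50, seq_len = 60, p_sub = 0.1,
                             seed = 1L) {
  stopifnot(inherits(panel, "species_panel"), p_sub >= 0, p_sub <= 0.95)
  all_sp <- c(panel$positive, panel$negative, panel$exempt)
  bad <- setdiff(unlist(families), all_sp)
  if (length(bad)) stop("family species outside the panel: ",
                        paste(unique(bad), collapse = ", "))
  structure(list(panel = panel, families = families, n_decoys = n_decoys,
                 seq_len = seq_len, p_sub = p_sub, seed = as.integer(seed)),
            class = "profile_scenario")
}

#' Default species panel for profile simulations
#'
#' Eight positive species (all required for confirmation), eight
#' negative, three exempt.
#'
#' @return A [species_panel()].
#' @export
default_profile_panel <- function() {
  species_panel(
    positive = paste0("pos", 1:8),
    negative = paste0("neg", 1:8),
    exempt = paste0("ex", 1:3))
}

#' Default planted families for profile simulations
#'
#' Five families probing the selection rules: three qualifying (present
#' in all eight positives; in 2 positives + 1 exempt; in 4 positives +
#' 1 exempt), one violating the minimum-positive rule (a single positive
#' species), and one present in a negative species.
#'
#' @param panel A [species_panel()].
#' @return Named list of member-species vectors.
#' @export
default_profile_families <- function(panel = default_profile_panel()) {
  list(
    famA = panel$positive,                                  # full presence
    famB = c(panel$positive[1:2], panel$exempt[1]),         # 2 positives + exempt
    famC = c(panel$positive[1:4], panel$exempt[2]),         # 4 positives + exempt
    famD = panel$positive[1],                               # < 2 positives
    famE = c(panel$positive[1:3], panel$negative[1])        # leaks into a negative
  )
}

#' Simulate proteomes with planted phyletic profiles
#'
#' @param scn A [profile_scenario()].
#' @return List with `proteomes` (data frame `id`, `species`, `seq`) and
#'   `truth` (data frame `gene_id`, `family` (`NA` for decoys),
#'   `species`).
#' @export
simulate_proteomes_with_profiles <- function(scn) {
  stopifnot(inherits(scn, "profile_scenario"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(scn$seed)
  all_sp <- c(scn$panel$positive, scn$panel$negative, scn$panel$exempt)
  rows <- list()
  for (fam in names(scn$families)) {
    members <- scn$families[[fam]]
    anc <- .random_protein(1, scn$seq_len)
    copy_idx <- stats::ave(seq_along(members), members, FUN = seq_along)
    for (k in seq_along(members)) {
      sp <- members[k]
      rows[[length(rows) + 1]] <- data.frame(
        id = paste0(fam, "_", sp, "_g", copy_idx[k]),
        species = sp,
        seq = .mutate_protein(anc, scn$p_sub),
        family = fam, stringsAsFactors = FALSE)
    }
  }
  if (scn$n_decoys > 0) {
    dsp <- sample(all_sp, scn$n_decoys, replace = TRUE)
    dseq <- .random_protein(scn$n_decoys, scn$seq_len)
    rows[[length(rows) + 1]] <- data.frame(
      id = paste0("decoy", seq_len(scn$n_decoys), "_", dsp),
      species = dsp, seq = dseq, family = NA_character_,
      stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, rows)
  list(proteomes = d[, c("id", "species", "seq")],
       truth = data.frame(gene_id = d$id, family = d$family,
                          species = d$species, stringsAsFactors = FALSE))
}

#' Scenario for simulated gene trees with a planted prokaryotic donor
#'
#' Emulates a eukaryotic gene acquired from a known prokaryotic phylum:
#' each phylum gets a random coalescent subtree, the phyla are joined in
#' a random order, and the eukaryotic clade is grafted a set number of
#' nodes inside the donor phylum's clade, separated from its prokaryotic
#' neighbours by a long stem branch. Homologue bit scores decay with
#' path distance from the eukaryotic clade (best hit ~300 bits) so the
#' coefficient grid spans realistic cutoffs.
#'
#' @param phyla Named integer vector: phylum -> leaf count.
#' @param donor Name of the donor phylum.
#' @param euk_size Number of eukaryotic leaves (>= 1).
#' @param depth Number of nodes inside the donor clade at which the
#'   eukaryotic clade is inserted (capped by clade depth).
#' @param stem_multiplier Eukaryotic stem length as a multiple of the
#'   mean prokaryotic branch length.
#' @param score_scale Approximate best-hit bit score.
#' @param score_decay Exponential decay rate of score with path distance.
#' @param score_noise_sd SD of additive score noise (bits).
#' @param seed Integer seed.
#' @return An `hgt_scenario` list.
#' @export
hgt_scenario <- function(phyla = c(Alphaproteobacteria = 5,
                                   Betaproteobacteria = 5,
                                   Gammaproteobacteria = 5,
                                   Firmicutes = 5,
                                   Bacteroidetes = 5),
                         donor = "Alphaproteobacteria",
                         euk_size = 3, depth = 3, stem_multiplier = 3,
                         score_scale = 300, score_decay = 0.3,
                         score_noise_sd = 5, seed = 1L) {
  stopifnot(donor %in% names(phyla), euk_size >= 1, all(phyla >= 1))
  structure(list(phyla = phyla, donor = donor, euk_size = euk_size,
                 depth = depth, stem_multiplier = stem_multiplier,
                 score_scale = score_scale, score_decay = score_decay,
                 score_noise_sd = score_noise_sd, seed = as.integer(seed)),
            class = "hgt_scenario")
}

#' Simulate a gene tree with a eukaryotic clade nested in a donor phylum
#'
#' @param scn An [hgt_scenario()].
#' @return List with `tree` ([ape::phylo], unrooted), `taxon_map` (data
#'   frame `id`, `domain`, `taxon`), `homologs` (data frame `id`,
#'   `score`, `domain`, `taxon`), and `donor` (the planted truth).
#' @export
simulate_donor_tree <- function(scn) {
  stopifnot(inherits(scn, "hgt_scenario"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(scn$seed)

  as_subtree <- function(labs) {
    if (length(labs) == 1) {
      return(structure(list(edge = matrix(c(2L, 1L), 1, 2),
                            tip.label = labs, edge.length = 0.5,
                            Nnode = 1L), class = "phylo"))
    }
    ape::rcoal(length(labs), tip.label = labs)
  }
  subtrees <- lapply(names(scn$phyla), function(ph)
    as_subtree(paste0(ph, "_", seq_len(scn$phyla[[ph]]))))
  names(subtrees) <- names(scn$phyla)

  ## graft the eukaryotic clade `depth` nodes inside the donor subtree,
  ## before the phyla are joined, so the planted nesting is guaranteed
  euk_labs <- paste0("Euk_", seq_len(scn$euk_size))
  donor_tree <- subtrees[[scn$donor]]
  mean_bl <- mean(donor_tree$edge.length[donor_tree$edge.length > 0])
  if (!is.finite(mean_bl) || mean_bl <= 0) mean_bl <- 0.5
  euk_clade <- as_subtree(euk_labs)
  euk_clade$root.edge <- scn$stem_multiplier * mean_bl

  ntip_d <- length(donor_tree$tip.label)
  if (ntip_d == 1) {
    attach_edge <- 1L
  } else {
    node <- ntip_d + 1L  # donor subtree root
    for (i in seq_len(scn$depth)) {
      ch <- donor_tree$edge[donor_tree$edge[, 1] == node, 2]
      internal <- ch[ch > ntip_d]
      node <- if (length(internal)) internal[sample.int(length(internal), 1)]
              else ch[sample.int(length(ch), 1)]
      if (node <= ntip_d) break
    }
    attach_edge <- which(donor_tree$edge[, 2] == node)
  }
  pos <- donor_tree$edge.length[attach_edge] / 2
  subtrees[[scn$donor]] <- ape::bind.tree(
    donor_tree, euk_clade, where = donor_tree$edge[attach_edge, 2],
    position = pos)

  ## join phyla in random order on a backbone
  ord <- sample(names(scn$phyla))
  backbone <- NULL
  for (ph in ord) {
    st <- subtrees[[ph]]
    st$root.edge <- 0.5
    backbone <- if (is.null(backbone)) st
                else ape::bind.tree(backbone, st, position = 0)
  }
  tree <- ape::unroot(backbone)

  taxon_map <- data.frame(
    id = tree$tip.label,
    domain = ifelse(grepl("^Euk_", tree$tip.label), "eukaryote", "prokaryote"),
    taxon = sub("_[0-9]+$", "", tree$tip.label),
    stringsAsFactors = FALSE)
  taxon_map$taxon[taxon_map$domain == "eukaryote"] <- ""

  ## homologue scores decay with path distance from the first euk leaf,
  ## anchored so the nearest prokaryote (the best hit) scores ~score_scale
  dmat <- cophenetic(tree)
  ref <- euk_labs[1]
  dist_from_euk <- dmat[ref, ]
  prok <- !grepl("^Euk_", names(dist_from_euk))
  d0 <- min(dist_from_euk[prok])
  score <- scn$score_scale * exp(-scn$score_decay * (dist_from_euk - d0)) +
    rnorm(length(dist_from_euk), 0, scn$score_noise_sd)
  score <- pmax(round(score, 1), 1)
  homologs <- data.frame(id = names(dist_from_euk),
                         score = unname(score),
                         domain = taxon_map$domain[match(names(dist_from_euk),
                                                         taxon_map$id)],
                         taxon = taxon_map$taxon[match(names(dist_from_euk),
                                                       taxon_map$id)],
                         stringsAsFactors = FALSE)
  list(tree = tree, taxon_map = taxon_map, homologs = homologs,
       donor = scn$donor)
}

#' Scenario for simulated fractionation proteomics
#'
#' Emulates a three-fraction density-gradient experiment with five
#' biological replicates. The default problem size mirrors a
#' whole-lysate quantification: 950 mitochondrial, 80 peroxisomal and
#' 3168 other proteins (4198 total), with 376 mitochondrial and 26
#' peroxisomal markers drawn from their classes. On the log2 scale a
#' protein's value is `class_mean[fraction] + protein offset +
#' replicate noise`; the class mean vectors encode how strongly each
#' class is enriched along the gradient (mitochondria increase towards
#' the densest fraction, the peroxisome profile peaks mid-gradient,
#' soluble contaminants decrease). A cell is missing with probability
#' `plogis(intercept + slope * log2 intensity)`; the steep negative
#' slope models a sharp instrument detection limit near 21.5 log2 units,
#' so low-abundance cells are preferentially missing (left-censored
#' MNAR; ~13% of cells overall at the defaults, concentrated in each
#' class's lightest fraction).
#'
#' @param n Named vector: truth-class sizes (`mito`, `perox`, `other`).
#' @param n_markers Named vector: markers per class (`mito`, `perox`).
#' @param class_means 3 x 3 numeric matrix (rows `mito`, `perox`,
#'   `other`; columns fractions) of log2 class mean profiles.
#' @param offset_sd SD of the per-protein abundance offset (log2).
#' @param replicate_sd SD of per-cell replicate noise (log2).
#' @param miss_intercept,miss_slope Logistic missingness coefficients on
#'   the log2-intensity scale.
#' @param fractions Fraction names (densities of the gradient steps).
#' @param n_reps Replicates per fraction.
#' @param seed Integer seed.
#' @return A `fractionation_scenario` list.
#' @export
fractionation_scenario <- function(n = c(mito = 950, perox = 80, other = 3168),
                                   n_markers = c(mito = 376, perox = 26),
                                   class_means = default_class_means(),
                                   offset_sd = 0.5, replicate_sd = 0.5,
                                   miss_intercept = 64.5, miss_slope = -3,
                                   fractions = c("Opt1015", "Opt1520", "Opt2030"),
                                   n_reps = 5, seed = 1L) {
  stopifnot(all(c("mito", "perox", "other") %in% names(n)),
            all(c("mito", "perox") %in% names(n_markers)),
            n_markers["mito"] <= n["mito"], n_markers["perox"] <= n["perox"],
            nrow(class_means) == 3, ncol(class_means) == length(fractions))
  structure(list(n = n, n_markers = n_markers, class_means = class_means,
                 offset_sd = offset_sd, replicate_sd = replicate_sd,
                 miss_intercept = miss_intercept, miss_slope = miss_slope,
                 fractions = fractions, n_reps = n_reps,
                 seed = as.integer(seed)),
            class = "fractionation_scenario")
}

#' Default log2 class mean profiles over the three gradient fractions
#' @return 3 x 3 matrix (rows mito/perox/other).
#' @export
default_class_means <- function() {
  m <- rbind(mito = c(21, 24, 27),
             perox = c(23.5, 27.5, 22),
             other = c(27, 24.5, 22))
  colnames(m) <- c("Opt1015", "Opt1520", "Opt2030")
  m
}

#' Simulate a fractionation intensity table with planted localisations
#'
#' @param scn A [fractionation_scenario()].
#' @return List with `table` (raw-scale `intensity_table` with MNAR
#'   missing cells), `truth` (data frame `protein`, `class`),
#'   `mito_markers`, `perox_markers`, `expected_missing_rate` (the
#'   scenario's analytic missingness rate, for calibration checks).
#' @export
simulate_fractionation_table <- function(scn) {
  stopifnot(inherits(scn, "fractionation_scenario"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(scn$seed)
  classes <- rep(c("mito", "perox", "other"),
                 times = scn$n[c("mito", "perox", "other")])
  nprot <- length(classes)
  ids <- sprintf("P%04d", seq_len(nprot))
  nf <- length(scn$fractions)
  cols <- paste0(rep(scn$fractions, each = scn$n_reps), "_r",
                 rep(seq_len(scn$n_reps), times = nf))
  offs <- rnorm(nprot, 0, scn$offset_sd)
  base <- scn$class_means[match(classes, rownames(scn$class_means)), ,
                          drop = FALSE]
  log2m <- base[, rep(seq_len(nf), each = scn$n_reps), drop = FALSE] + offs +
    matrix(rnorm(nprot * nf * scn$n_reps, 0, scn$replicate_sd),
           nprot, nf * scn$n_reps)
  dimnames(log2m) <- list(ids, cols)
  pmiss <- plogis(scn$miss_intercept + scn$miss_slope * log2m)
  miss <- matrix(runif(length(log2m)) < pmiss, nrow(log2m), ncol(log2m))
  raw <- 2^log2m
  raw[miss] <- NA
  mito_markers <- sample(ids[classes == "mito"], scn$n_markers["mito"])
  perox_markers <- sample(ids[classes == "perox"], scn$n_markers["perox"])
  list(table = intensity_table(raw),
       truth = data.frame(protein = ids, class = classes,
                          stringsAsFactors = FALSE),
       mito_markers = mito_markers,
       perox_markers = perox_markers,
       expected_missing_rate = mean(pmiss))
}
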