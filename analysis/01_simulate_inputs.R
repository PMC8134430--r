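#!/usr/bin/env Rscript

# Generates the planted-truth inputs for the three analyses and writes
# them as plain-text artifacts under results/inputs/, together with
# their truth tables. Every downstream script starts from these files,
# so the whole workflow can be reproduced without any external data.

suppressPackageStartupMessages(library(copresence))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(i <- which(args == "--seed"))) as.integer(args[i + 1]) else 1L

dir.create("results/inputs", showWarnings = FALSE, recursive = TRUE)

## 1. proteomes with planted phyletic profiles
scn <- profile_scenario(seed = seed)
sim <- simulate_proteomes_with_profiles(scn)
write_proteome_fasta(sim$proteomes, "results/inputs/proteomes.fasta")
write.table(sim$truth, "results/inputs/profile_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
panel_df <- data.frame(species = c(scn$panel$positive, scn$panel$negative,
                                        scn$panel$exempt),
                            role = rep(c("positive", "negative", "exempt"),
                                       c(length(scn$panel$positive),
                                         length(scn$panel$negative),
                                         length(scn$panel$exempt))))
write.table(panel_df, "results/inputs/panel.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("proteomes: ", nrow(sim$proteomes), " genes across ",
        length(unique(sim$proteomes$species)), " species, ",
        length(scn$families), " planted families + ", scn$n_decoys, " decoys")

## 2. gene tree with a eukaryotic clade nested in a donor phylum
dsim <- simulate_donor_tree(hgt_scenario(seed = seed))
write_newick(dsim$tree, "results/inputs/donor_tree.nwk")
write_taxon_map(dsim$taxon_map, "results/inputs/taxon_map.tsv")
write.table(dsim$homologs, "results/inputs/homolog_scores.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(dsim$donor, "results/inputs/planted_donor.txt")
message("donor tree: ", length(dsim$tree$tip.label), " leaves, euk clade of ",
        sum(dsim$taxon_map$domain == "eukaryote"),
        " nested in ", dsim$donor)

## 3. fractionation proteomics table at the deposited experiment's scale
fsim <- simulate_fractionation_table(fractionation_scenario(seed = seed))
write_intensity_tsv(fsim$table, "results/inputs/intensities.tsv")
writeLines(fsim$mito_markers, "results/inputs/mito_markers.txt")
writeLines(fsim$perox_markers, "results/inputs/perox_markers.txt")
write.table(fsim$truth, "results/inputs/fractionation_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("intensity table: ", nrow(fsim$table), " proteins x ",
        ncol(fsim$table), " samples, ",
        round(100 * mean(is.na(fsim$table)), 1), "% missing cells")
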