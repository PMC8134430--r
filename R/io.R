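## Readers/writers for the plain-text formats the pipelines touch:
## FASTA proteomes (+ sidecar species map), newick trees, outfmt-6 hit
## tables, taxon maps and fraction-proteomics intensity tables.

#' Read a proteome FASTA file
#'
#' Parses an amino-acid FASTA file into a proteome data frame. The species
#' of each record is taken from a sidecar id-to-species map
#' ([read_species_map()]) or, alternatively, extracted from the FASTA
#' header with `species_regex` (first capture group). Real proteome
#' releases mix many header dialects, so the sidecar map is the default
#' route.
#'
#' @param path Path to a FASTA file.
#' @param species_map Named character vector mapping sequence id to
#'   species token, or `NULL`.
#' @param species_regex Regular expression with one capture group applied
#'   to the full header line to extract the species, or `NULL`.
#' @return A data frame with columns `id`, `species`, `seq` (one row per
#'   record, input order preserved).
#' @export
read_proteome_fasta <- function(path, species_map = NULL, species_regex = NULL) {
  set <- Biostrings::readAAStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (length(ids) && anyDuplicated(ids))
    stop("duplicate sequence id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- as.character(set)
  if (any(nchar(seqs) == 0))
    stop("empty sequence body for id: ",
         paste(ids[nchar(seqs) == 0], collapse = ", "))
  species <- rep(NA_character_, length(ids))
  if (!is.null(species_regex)) {
    m <- regmatches(headers, regexec(species_regex, headers))
    species <- vapply(m, function(x) if (length(x) >= 2) x[2] else NA_character_, "")
  } else if (!is.null(species_map)) {
    species <- unname(species_map[ids])
  }
  data.frame(id = ids, species = species, seq = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write a proteome data frame to FASTA
#'
#' Headers are written as `id sp=<species>` so that round-tripping with
#' `read_proteome_fasta(species_regex = "sp=(\\\\S+)")` restores the
#' species column.
#'
#' @param proteome Data frame with columns `id`, `species`, `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(proteome, path) {
  stopifnot(all(c("id", "species", "seq") %in% names(proteome)))
  lines <- character(2L * nrow(proteome))
  if (nrow(proteome)) {
    lines[c(TRUE, FALSE)] <- paste0(">", proteome$id, " sp=", proteome$species)
    lines[c(FALSE, TRUE)] <- proteome$seq
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column id-to-species map
#'
#' @param path TSV with columns id, species (no header).
#' @return Named character vector (names = ids).
#' @export
read_species_map <- function(path) {
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                  col.names = c("id", "species"))
  if (anyDuplicated(d$id)) stop("duplicate id in species map")
  setNames(d$species, d$id)
}

#' Read a newick tree
#'
#' Thin wrapper around [ape::read.tree()] that checks the statement is
#' syntactically complete. Branch supports stored as internal node labels
#' (plain or quoted) survive the round trip; missing branch lengths stay
#' missing rather than becoming zero.
#'
#' @param path Path to a file holding one newick statement ending in ";".
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  if (!grepl(";", txt, fixed = TRUE))
    stop("newick statement not terminated by ';' in ", path)
  if (.paren_balance(txt) != 0L)
    stop("unbalanced parentheses in newick at character ",
         attr(.paren_balance(txt), "offset") %||% nchar(txt))
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) stop("newick parse error: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("newick parse error in ", path)
  if (any(!nzchar(tr$tip.label))) stop("empty leaf name in newick")
  tr
}

.paren_balance <- function(txt) {
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0)) {
    out <- -1L
    attr(out, "offset") <- which(depth < 0)[1]
    return(out)
  }
  depth[length(depth)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a tree to newick
#'
#' @param tree An [ape::phylo] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

## outfmt-6 column order (BLAST tabular default)
OUTFMT6_COLS <- c("qseqid", "sseqid", "pident", "length",
                  "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Read an outfmt-6-like hit table
#'
#' Columns follow the BLAST tabular default: qseqid, sseqid, pident,
#' length, qstart, qend, sstart, send, evalue, bitscore. Alignment
#' coordinates are 1-based inclusive throughout the package.
#'
#' @param path TSV path (no header).
#' @return Data frame of hits, validated (coordinates ordered, finite
#'   non-negative bitscores) and sorted by query then descending bitscore.
#' @export
read_hits_tsv <- function(path) {
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                  col.names = OUTFMT6_COLS)
  validate_hits(d)
}

#' Validate and sort a hit table
#'
#' @param hits Data frame with the outfmt-6 columns.
#' @return The hit table sorted by query id then descending bitscore.
#' @export
validate_hits <- function(hits) {
  stopifnot(all(OUTFMT6_COLS %in% names(hits)))
  if (any(!is.finite(hits$bitscore)) || any(hits$bitscore < 0))
    stop("bitscore must be finite and >= 0")
  if (any(hits$evalue < 0)) stop("evalue must be >= 0")
  if (any(hits$qstart > hits$qend) || any(hits$sstart > hits$send))
    stop("alignment coordinates must satisfy start <= end")
  hits[order(hits$qseqid, -hits$bitscore, hits$sseqid), , drop = FALSE]
}

#' Read a leaf taxonomy map
#'
#' @param path TSV with header columns `id`, `domain`, `taxon`. `domain`
#'   is "eukaryote" or "prokaryote"; every prokaryote needs a non-empty
#'   taxon (phylum or class token), eukaryotes may leave it empty.
#' @return Data frame with columns id, domain, taxon.
#' @export
read_taxon_map <- function(path) {
  d <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  validate_taxon_map(d)
}

#' Validate a taxonomy map
#' @param map Data frame with columns id, domain, taxon.
#' @return The validated map.
#' @export
validate_taxon_map <- function(map) {
  stopifnot(all(c("id", "domain", "taxon") %in% names(map)))
  if (anyDuplicated(map$id)) stop("duplicate id in taxon map")
  if (!all(map$domain %in% c("eukaryote", "prokaryote")))
    stop("domain must be 'eukaryote' or 'prokaryote'")
  bad <- map$domain == "prokaryote" & (is.na(map$taxon) | !nzchar(map$taxon))
  if (any(bad))
    stop("prokaryote entries need a taxon: ",
         paste(map$id[bad], collapse = ", "))
  map
}

#' Write a taxonomy map
#' @param map Data frame with columns id, domain, taxon.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxon_map <- function(map, path) {
  write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a fraction-proteomics intensity table
#'
#' The TSV must have a first column of protein ids and remaining columns
#' named `<fraction>_<replicate>` (e.g. `Opt1015_r1`). Missing cells are
#' encoded as the empty string or `NaN`/`NA`; a literal 0 is a valid
#' measured value unless `zero_is_missing = TRUE` (label-free exports
#' vary in how they encode censoring).
#'
#' @param path TSV path with a header row.
#' @param zero_is_missing Treat literal 0 as missing. Default `FALSE`.
#' @return An `intensity_table`: a numeric matrix (proteins x samples,
#'   `NA` = missing) with attributes `fractions` and `replicates`
#'   parallel to its columns.
#' @export
read_intensity_tsv <- function(path, zero_is_missing = FALSE) {
  d <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                  check.names = FALSE, na.strings = c("", "NA", "NaN"))
  if (ncol(d) < 2) stop("intensity table needs a protein column plus samples")
  ids <- as.character(d[[1]])
  if (anyDuplicated(ids))
    stop("duplicate protein id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (zero_is_missing) m[!is.na(m) & m == 0] <- NA
  intensity_table(m)
}

#' Construct an intensity table from a matrix
#'
#' @param m Numeric matrix, rows = proteins, columns named
#'   `<fraction>_<replicate>`; `NA` marks missing cells.
#' @return An `intensity_table` object.
#' @export
intensity_table <- function(m) {
  stopifnot(is.matrix(m), !is.null(colnames(m)), !is.null(rownames(m)))
  parsed <- regmatches(colnames(m), regexec("^(.+)_([A-Za-z]*[0-9]+)$", colnames(m)))
  bad <- vapply(parsed, length, 0L) != 3L
  if (any(bad))
    stop("column name not of the form <fraction>_<replicate>: ",
         paste(colnames(m)[bad], collapse = ", "))
  if (any(!is.na(m) & m < 0)) stop("negative intensity")
  structure(m,
            fractions = vapply(parsed, `[`, "", 2L),
            replicates = vapply(parsed, `[`, "", 3L),
            class = c("intensity_table", "matrix", "array"))
}

#' @export
print.intensity_table <- function(x, ...) {
  cat("intensity_table:", nrow(x), "proteins x", ncol(x), "samples (",
      length(unique(attr(x, "fractions"))), "fractions ),",
      sum(is.na(x)), "missing cells\n")
  invisible(x)
}

#' Write an intensity table to TSV
#'
#' Missing cells are written as `NA`.
#'
#' @param tab An `intensity_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intensity_tsv <- function(tab, path) {
  d <- data.frame(protein = rownames(tab), as.data.frame(unclass(tab)),
                  check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fractions of an intensity table
#' @param tab An `intensity_table`.
#' @return Character vector of fraction names, one per column.
#' @export
fractions_of <- function(tab) attr(tab, "fractions")
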