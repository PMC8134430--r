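## All-vs-all protein similarity search at desk scale: Smith-Waterman
## local alignment (BLOSUM62, affine gaps 11/1) via Biostrings, with
## bit scores and E-values from the Karlin-Altschul approximation.
## Production-size inputs bypass this and supply an outfmt-6 file.

## Gapped Karlin-Altschul parameters for BLOSUM62, gap open 11 / extend 1
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Bit score from a raw Smith-Waterman score
#'
#' Uses the gapped Karlin-Altschul parameters for BLOSUM62 with affine
#' gap penalties 11/1 (lambda = 0.267, K = 0.041).
#'
#' @param raw Raw alignment score(s).
#' @return Bit score(s).
#' @export
bitscore_from_raw <- function(raw) (KA_LAMBDA * raw - log(KA_K)) / log(2)

#' E-value from a bit score
#'
#' @param bits Bit score(s).
#' @param m Query length.
#' @param n Total residues in the searched database.
#' @return Expected number of chance hits at least this strong.
#' @export
evalue_from_bits <- function(bits, m, n) m * n * 2^(-bits)

#' All-vs-all protein similarity search
#'
#' Compares every sequence of every proteome against all sequences
#' (self-hits included) by Smith-Waterman local alignment with BLOSUM62
#' and affine gap penalties (open 11, extend 1), converting raw scores to
#' bits and E-values with the Karlin-Altschul approximation. Hits with
#' E-value above `evalue_cutoff` are discarded; full alignments (percent
#' identity, 1-based inclusive coordinates) are computed only for
#' retained pairs. For large inputs compute hits externally (BLAST
#' outfmt 6) and feed them to [read_hits_tsv()] instead; downstream
#' steps take either source.
#'
#' @param proteomes Data frame with columns `id`, `species`, `seq`
#'   covering at least two species, ids unique across all species.
#' @param evalue_cutoff Maximum E-value of a reported hit (> 0).
#' @return Hit table in outfmt-6 column order, sorted by query then
#'   descending bit score.
#' @export
all_vs_all_search <- function(proteomes, evalue_cutoff = 1e-5) {
  stopifnot(evalue_cutoff > 0)
  if (!nrow(proteomes)) stop("empty proteome set")
  if (any(!nzchar(proteomes$seq))) stop("empty sequence in proteome")
  if (anyDuplicated(proteomes$id))
    stop("duplicate ids across proteomes: ",
         paste(unique(proteomes$id[duplicated(proteomes$id)]), collapse = ", "))
  if (length(unique(proteomes$species)) < 2)
    stop("need proteomes from at least two species")

  seqs <- Biostrings::AAStringSet(setNames(proteomes$seq, proteomes$id))
  data("BLOSUM62", package = "Biostrings", envir = environment())
  mat <- get("BLOSUM62", envir = environment())
  db_n <- sum(nchar(proteomes$seq))

  res <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    raw <- Biostrings::pairwiseAlignment(
      pattern = seqs, subject = seqs[[i]], type = "local",
      substitutionMatrix = mat, gapOpening = 11, gapExtension = 1,
      scoreOnly = TRUE)
    bits <- bitscore_from_raw(raw)
    ev <- evalue_from_bits(bits, nchar(proteomes$seq[i]), db_n)
    keep <- which(ev <= evalue_cutoff)
    if (!length(keep)) next
    aln <- Biostrings::pairwiseAlignment(
      pattern = seqs[keep], subject = seqs[[i]], type = "local",
      substitutionMatrix = mat, gapOpening = 11, gapExtension = 1)
    res[[i]] <- data.frame(
      qseqid = proteomes$id[i],
      sseqid = proteomes$id[keep],
      pident = round(Biostrings::pid(aln, type = "PID1"), 2),
      length = Biostrings::nchar(aln),
      ## pattern = subject sequences of the hit table, subject = query
      qstart = Biostrings::start(Biostrings::subject(aln)),
      qend = Biostrings::end(Biostrings::subject(aln)),
      sstart = Biostrings::start(Biostrings::pattern(aln)),
      send = Biostrings::end(Biostrings::pattern(aln)),
      evalue = ev[keep],
      bitscore = round(bits[keep], 1),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(matrix(nrow = 0, ncol = 10,
                                             dimnames = list(NULL, OUTFMT6_COLS)))
  validate_hits(out)
}
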