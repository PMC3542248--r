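# Six-frame open-reading-frame prediction for transcripts lacking coding
# annotation, and coding-sequence extraction for annotated ones.
#
# ORFs are maximal stop-free codon stretches (stop-to-stop convention, as
# in EMBOSS getorf's default), not ATG-initiated: assembled transcripts are
# frequently 5'-truncated, and requiring a start codon would discard real
# coding sequence. Codons containing N break an ORF like a stop does, so
# no predicted CDS ever contains an ambiguous codon.

#' Predict open reading frames in all six frames
#'
#' Scans each reading frame of the forward and reverse-complement strands
#' for maximal stop-free codon stretches under the standard genetic code
#' and reports those strictly longer than \code{minNt} nucleotides
#' (the screen's default keeps predicted CDS "longer than 300 bp").
#' Coordinates are 0-based half-open on the forward strand.
#'
#' @param x A \code{TranscriptSet}, a single sequence as a character
#'   string, or a \code{DNAString}.
#' @param minNt Minimum ORF length in nucleotides, exclusive (an ORF of
#'   exactly \code{minNt} is not reported).
#' @return \code{data.frame} with columns \code{transcript_id},
#'   \code{frame} (\code{+1,+2,+3,-1,-2,-3}), \code{start}, \code{end},
#'   \code{nt_length}, \code{cds}, sorted per transcript by length
#'   descending (ties: frame order \code{+1,+2,+3,-1,-2,-3}, then smaller
#'   start).
#' @examples
#' findOrfs(paste(rep("AAA", 30), collapse = ""), minNt = 0)
#' @export
findOrfs <- function(x, minNt = 300) {
  if (is(x, "TranscriptSet")) {
    seqs <- as.character(transcriptSeqs(x))
  } else if (is(x, "DNAString")) {
    seqs <- setNames(as.character(x), "seq1")
  } else {
    seqs <- as.character(x)
    if (is.null(names(seqs)))
      names(seqs) <- paste0("seq", seq_along(seqs))
  }
  out <- lapply(names(seqs), function(id)
    .findOrfsOne(id, seqs[[id]], minNt))
  res <- do.call(rbind, out)
  if (is.null(res)) res <- .emptyOrfTable()
  res
}

#' @noRd
.emptyOrfTable <- function() {
  data.frame(transcript_id = character(), frame = integer(),
             start = integer(), end = integer(), nt_length = integer(),
             cds = character(), stringsAsFactors = FALSE)
}

#' @noRd
.findOrfsOne <- function(id, seq, minNt) {
  L <- nchar(seq)
  if (L < 3L) return(NULL)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  rows <- list()
  frameOrder <- c(1L, 2L, 3L, -1L, -2L, -3L)
  for (fr in frameOrder) {
    s <- if (fr > 0) seq else rc
    off <- abs(fr) - 1L
    n <- (L - off) %/% 3L
    if (n < 1L) next
    codons <- substring(s, off + seq_len(n) * 3L - 2L, off + seq_len(n) * 3L)
    tab <- .codonTables()
    idx <- unname(tab$codonIndex[codons])
    # breakers: stop codons and any codon containing N (idx is NA then)
    brk <- is.na(idx) | !tab$sense[ifelse(is.na(idx), 1L, idx)]
    runs <- rle(!brk)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    keep <- which(runs$values)
    for (k in keep) {
      c0 <- starts[k]; c1 <- ends[k]  # codon positions, 1-based inclusive
      ntLen <- (c1 - c0 + 1L) * 3L
      if (ntLen <= minNt) next
      sStart <- off + (c0 - 1L) * 3L        # 0-based on the scanned strand
      sEnd <- off + c1 * 3L
      if (fr > 0) { fStart <- sStart; fEnd <- sEnd }
      else { fStart <- L - sEnd; fEnd <- L - sStart }
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = id, frame = fr, start = fStart, end = fEnd,
        nt_length = ntLen,
        cds = paste(codons[c0:c1], collapse = ""),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  res <- do.call(rbind, rows)
  fRank <- match(res$frame, frameOrder)
  res[order(-res$nt_length, fRank, res$start), , drop = FALSE]
}

#' Longest qualifying ORF of a transcript
#'
#' @inheritParams findOrfs
#' @return One-row \code{data.frame} (the longest ORF; ties broken by
#'   frame order \code{+1,+2,+3,-1,-2,-3} then smaller start) or
#'   \code{NULL} when no ORF exceeds \code{minNt}.
#' @export
longestOrf <- function(x, minNt = 300) {
  orfs <- findOrfs(x, minNt)
  if (nrow(orfs) == 0L) return(NULL)
  orfs[1L, , drop = FALSE]  # findOrfs already sorts by the tie rule
}

#' Extract the annotated coding sequence of a transcript
#'
#' Slices \code{[coding_start, coding_end)} from the forward strand,
#' reverse-complements when \code{strand} is \code{-1}, truncates at the
#' 3' end to a whole number of codons, and trims one trailing stop codon
#' if present (an annotated CDS often includes its terminator; internal
#' stops are left in place and caught by alignment QC).
#'
#' @param transcripts A \code{TranscriptSet} with annotation.
#' @param transcriptId Which transcript to extract.
#' @return The coding sequence as a character string.
#' @export
extractAnnotatedCds <- function(transcripts, transcriptId) {
  ann <- codingAnnotation(transcripts)
  row <- ann[ann$transcript_id == transcriptId, , drop = FALSE]
  if (nrow(row) == 0L)
    stop("no annotation for transcript ", sQuote(transcriptId))
  row <- row[1L, ]
  seq <- transcriptSeqs(transcripts)[[transcriptId]]
  cds <- Biostrings::subseq(seq, start = row$coding_start + 1L,
                            end = row$coding_end)
  if (row$strand == -1L) cds <- Biostrings::reverseComplement(cds)
  cds <- as.character(cds)
  n <- (nchar(cds) %/% 3L) * 3L
  cds <- substr(cds, 1L, n)
  # trim one terminal stop codon
  if (n >= 3L) {
    last <- substr(cds, n - 2L, n)
    if (last %in% c("TAA", "TAG", "TGA")) cds <- substr(cds, 1L, n - 3L)
  }
  cds
}
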