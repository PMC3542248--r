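# Protein-guided codon alignment of an ortholog pair, and the screen's
# alignment QC: pairs with unexpected stop codons, ambiguous alignments
# (operationalized as > 5% N-containing columns) or compared length below
# 200 bp (300 bp for ORF-predicted pairs) are discarded.
#
# The two coding sequences are aligned as proteins with a global
# Needleman-Wunsch (BLOSUM62, gap open 10 / extend 1) and back-translated
# so every amino-acid column becomes its source codon or "---". For two
# sequences this is the same optimum a multiple aligner would return,
# and it is deterministic.

#' Align two coding sequences codon-aware
#'
#' @param cdsA,cdsB Coding sequences (multiples of 3, at least one codon).
#'   Codons containing \code{N} translate to \code{X} and their columns
#'   are flagged ambiguous. A stop codon anywhere in either CDS marks the
#'   alignment \code{fail(stop_codon)} (it is still built, so the offending
#'   pair can be inspected).
#' @param pairIdent Identifier stored on the result.
#' @param gapOpen,gapExt Affine gap penalties for the protein alignment.
#' @param maxAmbiguous Maximum tolerated fraction of ambiguous columns
#'   among ungapped ones before \code{fail(ambiguous)}.
#' @return A [CodonAlignment-class]. The \code{status}/\code{reason}
#'   reflect stop-codon and ambiguity checks; apply [qcFilter()] for the
#'   length rule.
#' @examples
#' aln <- alignCodonPair("ATGAAACCC", "ATGAAACCC")
#' comparedCodons(aln)
#' @export
alignCodonPair <- function(cdsA, cdsB, pairIdent = "pair",
                           gapOpen = 10, gapExt = 1,
                           maxAmbiguous = 0.05) {
  codA <- .checkCds(cdsA, "cdsA")
  codB <- .checkCds(cdsB, "cdsB")
  stopA <- .hasInternalStop(codA)
  stopB <- .hasInternalStop(codB)
  aaA <- .translateCodons(codA)
  aaB <- .translateCodons(codB)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(paste(aaA, collapse = "")),
    Biostrings::AAString(paste(aaB, collapse = "")),
    substitutionMatrix = .blosum62(),
    gapOpening = gapOpen, gapExtension = gapExt,
    type = "global")
  pA <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  pB <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  backA <- .backTranslate(pA, codA)
  backB <- .backTranslate(pB, codB)
  ungapped <- pA != "-" & pB != "-"
  ambiguous <- ungapped & (grepl("N", backA, fixed = TRUE) |
                           grepl("N", backB, fixed = TRUE))
  nUngapped <- sum(ungapped)
  nAmb <- sum(ambiguous)
  status <- "pass"; reason <- ""
  if (stopA || stopB) {
    status <- "fail"; reason <- "stop_codon"
  } else if (nUngapped > 0 && nAmb / nUngapped > maxAmbiguous) {
    status <- "fail"; reason <- "ambiguous"
  }
  new("CodonAlignment", pairId = pairIdent,
      alnA = paste(backA, collapse = ""),
      alnB = paste(backB, collapse = ""),
      comparedCodons = as.integer(nUngapped - nAmb),
      ambiguousCodons = as.integer(nAmb),
      status = status, reason = reason)
}

#' @noRd
.checkCds <- function(cds, what) {
  cds <- .normalizeNt(cds, what)
  if (nchar(cds) < 3L || nchar(cds) %% 3L != 0L)
    stop(what, " must be a nonempty multiple of 3")
  .splitCodons(cds)
}

#' @noRd
.hasInternalStop <- function(codons) {
  any(codons %in% c("TAA", "TAG", "TGA"))
}

#' @noRd
.translateCodons <- function(codons) {
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"  # codons containing N
  unname(aa)
}

#' @noRd
.backTranslate <- function(alignedAA, codons) {
  out <- character(length(alignedAA))
  j <- 0L
  for (i in seq_along(alignedAA)) {
    if (alignedAA[i] == "-") out[i] <- "---"
    else { j <- j + 1L; out[i] <- codons[j] }
  }
  if (j != length(codons))
    stop("internal error: back-translation consumed ", j, " of ",
         length(codons), " codons")
  out
}

#' Apply the screen's alignment QC rule
#'
#' Fails an alignment whose pair carried an unexpected stop codon, whose
#' ambiguous-column fraction exceeded the tolerance (both already assessed
#' by [alignCodonPair()]), or whose compared length in nucleotides is
#' shorter than the source-specific minimum: 200 bp for annotated pairs,
#' 300 bp for ORF-predicted pairs (strict: 198 bp fails, 201 bp passes a
#' 200 bp rule).
#'
#' @param alignment A \code{CodonAlignment}.
#' @param source \code{"annotated"} or \code{"orf_predicted"}.
#' @param minNtAnnotated,minNtOrf Length thresholds in nucleotides.
#' @return The alignment with final \code{status}/\code{reason}; query via
#'   [qcStatus()].
#' @export
qcFilter <- function(alignment, source = c("annotated", "orf_predicted"),
                     minNtAnnotated = 200, minNtOrf = 300) {
  source <- match.arg(source)
  if (alignment@status == "fail") return(alignment)
  minNt <- if (source == "annotated") minNtAnnotated else minNtOrf
  if (alignment@comparedCodons * 3L < minNt) {
    alignment@status <- "fail"
    alignment@reason <- "too_short"
  }
  alignment
}

#' Write a codon alignment as a 2-record FASTA
#'
#' @param alignment A \code{CodonAlignment}.
#' @param path Output path.
#' @param ids Record names (default derived from the pair id).
#' @return \code{path}, invisibly.
#' @export
writeAlignmentFasta <- function(alignment, path,
                                ids = paste0(alignment@pairId,
                                             c("_a", "_b"))) {
  seqs <- Biostrings::BStringSet(setNames(c(alignment@alnA,
                                            alignment@alnB), ids))
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

# compared codon index pairs for the estimators: columns ungapped in both
# rows, free of N, both sense codons
#' @noRd
.comparedIndices <- function(alignment) {
  ca <- .splitCodons(alignment@alnA)
  cb <- .splitCodons(alignment@alnB)
  tab <- .codonTables()
  ia <- unname(tab$codonIndex[ca])
  ib <- unname(tab$codonIndex[cb])
  ok <- !is.na(ia) & !is.na(ib) & tab$sense[ifelse(is.na(ia), 1L, ia)] &
    tab$sense[ifelse(is.na(ib), 1L, ib)]
  list(ia = ia[ok], ib = ib[ok])
}
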