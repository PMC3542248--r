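#' TranscriptSet: one species' transcripts with optional coding annotation
#'
#' A thin S4 container around a [Biostrings::DNAStringSet] holding the
#' transcripts of a single species, together with a species tag and an
#' optional annotation table mapping transcripts to reference
#' proteins/genes with coding coordinates. All coordinates are 0-based
#' half-open on the transcript forward strand; annotation files in 1-based
#' inclusive dialects must be converted before loading.
#'
#' @slot seqs A \code{DNAStringSet}; names are transcript ids (unique,
#'   nonempty). Sequences are upper-case over \code{A,C,G,T,N}.
#' @slot species Single character tag naming the species.
#' @slot annotation \code{data.frame} with columns \code{transcript_id},
#'   \code{ref_gene_id}, \code{ref_protein_id}, \code{coding_start},
#'   \code{coding_end}, \code{strand} (\code{+1}/\code{-1}) and optional
#'   \code{ref_start}, \code{ref_end} (amino-acid interval on the reference
#'   protein, used when collapsing splice-variant redundancy). May have
#'   zero rows.
#'
#' @seealso [readTranscripts()], [readAnnotationTable()]
#' @export
setClass("TranscriptSet",
         representation(seqs = "DNAStringSet",
                        species = "character",
                        annotation = "data.frame"))

.annotationCols <- c("transcript_id", "ref_gene_id", "ref_protein_id",
                     "coding_start", "coding_end", "strand")

setValidity("TranscriptSet", function(object) {
  ids <- names(object@seqs)
  if (is.null(ids) || any(!nzchar(ids)))
    return("all transcripts must have nonempty ids")
  if (anyDuplicated(ids))
    return(paste0("duplicate transcript id: ", ids[duplicated(ids)][1]))
  if (length(object@species) != 1L || !nzchar(object@species))
    return("species must be a single nonempty string")
  ann <- object@annotation
  if (!all(.annotationCols %in% names(ann)))
    return("annotation must carry the standard columns")
  if (nrow(ann)) {
    bad <- !(ann$transcript_id %in% ids)
    if (any(bad))
      return(paste0("annotation row for unknown transcript: ",
                    ann$transcript_id[bad][1]))
    len <- width(object@seqs)[match(ann$transcript_id, ids)]
    if (any(ann$coding_end - ann$coding_start <= 0))
      return("coding_end must exceed coding_start")
    if (any(ann$coding_start < 0) || any(ann$coding_end > len))
      return("coding coordinates out of transcript bounds")
    if (!all(ann$strand %in% c(1L, -1L)))
      return("strand must be +1 or -1")
  }
  TRUE
})

#' Construct a TranscriptSet
#'
#' @param seqs Named character vector or \code{DNAStringSet} of transcript
#'   sequences. Lower case is accepted and normalized; \code{U} is mapped
#'   to \code{T}; characters outside \code{A,C,G,T,N} are rejected.
#' @param species Species tag.
#' @param annotation Optional annotation \code{data.frame}
#'   (see [TranscriptSet-class]); defaults to an empty table.
#' @return A \code{TranscriptSet}.
#' @examples
#' ts <- TranscriptSet(c(t1 = "atgaaaccc"), species = "frogA")
#' transcriptIds(ts)
#' @export
TranscriptSet <- function(seqs, species, annotation = emptyAnnotation()) {
  if (is.character(seqs)) {
    seqs <- vapply(seqs, .normalizeNt, character(1))
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  new("TranscriptSet", seqs = seqs, species = species,
      annotation = annotation)
}

#' An empty annotation table with the standard columns
#' @return Zero-row \code{data.frame} with the annotation columns.
#' @export
emptyAnnotation <- function() {
  data.frame(transcript_id = character(), ref_gene_id = character(),
             ref_protein_id = character(), coding_start = integer(),
             coding_end = integer(), strand = integer(),
             stringsAsFactors = FALSE)
}

# normalize a nucleotide string: upper-case, U->T, strict alphabet
#' @noRd
.normalizeNt <- function(x, what = "sequence") {
  x <- chartr("u", "T", toupper(x))
  x <- chartr("U", "T", x)
  bad <- regexpr("[^ACGTN]", x)
  if (bad > 0)
    stop(what, " contains invalid character '",
         substr(x, bad, bad), "' at position ", bad)
  x
}

#' CodonAlignment: a back-translated pairwise codon alignment
#'
#' Result of protein-guided alignment of two coding sequences: both rows
#' have equal length, a multiple of 3, and gaps occur only as whole-codon
#' \code{---} triplets. Columns whose codons contain \code{N} are flagged
#' ambiguous and excluded from all downstream counting.
#'
#' @slot pairId Identifier of the ortholog pair.
#' @slot alnA,alnB Aligned codon strings (gap = \code{---}).
#' @slot comparedCodons Number of columns compared downstream: ungapped in
#'   both rows and free of ambiguity.
#' @slot ambiguousCodons Number of ungapped columns excluded as ambiguous.
#' @slot status \code{"pass"} or \code{"fail"}.
#' @slot reason Failure reason (\code{stop_codon}, \code{too_short},
#'   \code{ambiguous}) or \code{""}.
#' @export
setClass("CodonAlignment",
         representation(pairId = "character", alnA = "character",
                        alnB = "character", comparedCodons = "integer",
                        ambiguousCodons = "integer", status = "character",
                        reason = "character"))

setValidity("CodonAlignment", function(object) {
  a <- object@alnA; b <- object@alnB
  if (nchar(a) != nchar(b)) return("aligned rows differ in length")
  if (nchar(a) %% 3 != 0) return("alignment length not a multiple of 3")
  ca <- .splitCodons(a); cb <- .splitCodons(b)
  partial <- function(x) grepl("-", x) & x != "---"
  if (any(partial(ca)) || any(partial(cb)))
    return("gaps must span whole codons")
  if (!object@status %in% c("pass", "fail")) return("bad status")
  TRUE
})

#' @noRd
.splitCodons <- function(x) {
  if (!nzchar(x)) return(character())
  substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
}

#' KaKsResult: per-pair substitution-rate estimates
#'
#' Site counts, pathway-averaged difference counts, kappa, Ka, Ks and the
#' Ka/Ks ratio for one ortholog pair, plus the substitution-class bucket
#' used in the screen's accounting: \code{identical} (no differences),
#' \code{syn_only}/\code{nonsyn_only} (one type only; ratio undefined) and
#' \code{both}, the only bucket for which a ratio is reported.
#'
#' @slot pairId Pair identifier.
#' @slot method \code{"NG86"} or \code{"YN"}.
#' @slot S,N Expected synonymous / nonsynonymous site counts.
#' @slot Sd,Nd Pathway-averaged synonymous / nonsynonymous differences.
#' @slot kappa Transition/transversion rate ratio used (1 for NG86).
#' @slot Ka,Ks Corrected per-site substitution estimates (\code{NA} when
#'   saturated).
#' @slot ratio Ka/Ks, or \code{NA} when undefined.
#' @slot bucket One of \code{identical}, \code{syn_only},
#'   \code{nonsyn_only}, \code{both}.
#' @slot excludedColumns Columns dropped because every mutational path
#'   crossed a stop codon.
#' @slot warnings Character vector of estimator warnings.
#' @export
setClass("KaKsResult",
         representation(pairId = "character", method = "character",
                        S = "numeric", N = "numeric",
                        Sd = "numeric", Nd = "numeric",
                        kappa = "numeric", Ka = "numeric", Ks = "numeric",
                        ratio = "numeric", bucket = "character",
                        excludedColumns = "integer",
                        warnings = "character"))

setValidity("KaKsResult", function(object) {
  if (object@S < 0 || object@N < 0) return("site counts must be >= 0")
  if (object@Sd < 0 || object@Nd < 0)
    return("difference counts must be >= 0")
  if (!object@bucket %in% c("identical", "syn_only", "nonsyn_only", "both"))
    return("bad bucket")
  if (!object@method %in% c("NG86", "YN")) return("bad method")
  TRUE
})

#' ScreenReport: end-to-end pipeline result
#'
#' Holds the per-pair results table of a full screen run together with the
#' stage-by-stage accounting (pairs found, QC failures by reason, paralog
#' filtering, bucket and class tallies) and the GO-level summaries.
#'
#' @slot results \code{data.frame} of per-pair Ka/Ks results and classes.
#' @slot counts Named list of stage counts.
#' @slot termSummary \code{data.frame} of per-GO-term mean Ka/Ks.
#' @slot categoryDistribution \code{data.frame} of level-rollup percentages.
#' @slot screenHits \code{data.frame} from the two-step a-priori screen.
#' @slot config The configuration list the run used (echoed verbatim).
#' @export
setClass("ScreenReport",
         representation(results = "data.frame", counts = "list",
                        termSummary = "data.frame",
                        categoryDistribution = "data.frame",
                        screenHits = "data.frame", config = "list"))
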