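# Readers and writers for the formats the pipeline touches: FASTA
# transcripts, the coding-annotation table, and the GO mapping/edge tables.
# All tables are headered, tab-delimited, UTF-8.

#' Read a species' transcripts from FASTA
#'
#' Sequences are upper-cased, \code{U} is mapped to \code{T}, and any
#' character outside \code{A,C,G,T,N} is rejected with its position.
#' Duplicate record ids are an error.
#'
#' @param path Path to a FASTA file.
#' @param species Species tag to attach.
#' @return A [TranscriptSet-class].
#' @export
readTranscripts <- function(path, species) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("cannot read FASTA ", path, ": ",
                             conditionMessage(e)))
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(seqs))  # id = first whitespace token
  if (anyDuplicated(ids))
    stop("duplicate transcript id in ", path, ": ",
         ids[duplicated(ids)][1])
  chr <- as.character(seqs)
  chr <- vapply(seq_along(chr), function(i)
    tryCatch(.normalizeNt(chr[i]),
             error = function(e) stop("record ", sQuote(ids[i]), ": ",
                                      conditionMessage(e), call. = FALSE)),
    character(1))
  out <- Biostrings::DNAStringSet(chr)
  names(out) <- ids
  new("TranscriptSet", seqs = out, species = species,
      annotation = emptyAnnotation())
}

#' Write transcripts to FASTA
#'
#' @param x A \code{TranscriptSet} (or named \code{DNAStringSet}).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeTranscripts <- function(x, path) {
  seqs <- if (is(x, "TranscriptSet")) transcriptSeqs(x) else x
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Read a coding-annotation table
#'
#' Expects a headered TSV with columns \code{transcript_id},
#' \code{ref_gene_id}, \code{ref_protein_id}, \code{coding_start},
#' \code{coding_end}, \code{strand} and optionally \code{ref_start},
#' \code{ref_end}. Coordinates are 0-based half-open on the transcript
#' forward strand; \code{strand} is \code{+}/\code{-} or \code{+1}/\code{-1}.
#' Rows referring to transcripts absent from \code{transcripts} are
#' reported and skipped; rows with out-of-bounds coordinates are an error.
#'
#' @param path Path to the TSV.
#' @param transcripts Optional \code{TranscriptSet} to validate against and
#'   attach the annotation to.
#' @return If \code{transcripts} is supplied, the \code{TranscriptSet} with
#'   annotation attached; otherwise the validated \code{data.frame}.
#' @export
readAnnotationTable <- function(path, transcripts = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) {
    ann <- emptyAnnotation()
  } else {
    need <- .annotationCols
    if (!all(need %in% names(tab)))
      stop("annotation table lacks columns: ",
           paste(setdiff(need, names(tab)), collapse = ", "))
    strand <- as.character(tab$strand)
    sMap <- c("+" = 1L, "-" = -1L, "+1" = 1L, "-1" = -1L, "1" = 1L)
    sVal <- unname(sMap[strand])
    for (col in c("coding_start", "coding_end")) {
      v <- suppressWarnings(as.integer(tab[[col]]))
      if (anyNA(v))
        stop("malformed ", col, " at line ",
             which(is.na(v))[1] + 1L)  # +1 for the header line
      tab[[col]] <- v
    }
    if (anyNA(sVal))
      stop("malformed strand at line ", which(is.na(sVal))[1] + 1L)
    tab$strand <- sVal
    bad <- tab$coding_end <= tab$coding_start
    if (any(bad))
      stop("coding_end <= coding_start at line ", which(bad)[1] + 1L)
    ann <- tab
  }
  if (is.null(transcripts)) return(ann)
  ids <- transcriptIds(transcripts)
  unknown <- !(ann$transcript_id %in% ids)
  if (any(unknown)) {
    warning(sum(unknown), " annotation row(s) for unknown transcripts ",
            "skipped (first: ", ann$transcript_id[unknown][1], ")")
    ann <- ann[!unknown, , drop = FALSE]
  }
  if (nrow(ann)) {
    len <- width(transcriptSeqs(transcripts))[match(ann$transcript_id, ids)]
    oob <- ann$coding_start < 0 | ann$coding_end > len
    if (any(oob))
      stop("coding coordinates out of bounds for transcript ",
           ann$transcript_id[oob][1])
  }
  codingAnnotation(transcripts) <- ann
  transcripts
}

#' Read a GO annotation table (gene to term)
#'
#' @param path Headered TSV with columns \code{gene_id}, \code{term_id}
#'   (one row per gene-term link).
#' @return \code{data.frame} with those two columns, deduplicated.
#' @export
readGOAnnotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "term_id") %in% names(tab)))
    stop("GO annotation table needs columns gene_id, term_id")
  unique(tab[, c("gene_id", "term_id")])
}

#' Read a GO edge table
#'
#' @param path Headered TSV with columns \code{child}, \code{parent},
#'   \code{relation} (e.g. \code{is_a}), \code{namespace}.
#' @return \code{data.frame} with those columns. The \code{is_a} subgraph
#'   is checked to be acyclic.
#' @export
readGOEdges <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("child", "parent", "relation", "namespace")
  if (!all(need %in% names(tab)))
    stop("GO edge table needs columns: ", paste(need, collapse = ", "))
  isa <- tab[tab$relation == "is_a", , drop = FALSE]
  if (nrow(isa)) {
    g <- igraph::graph_from_data_frame(isa[, c("child", "parent")])
    if (!igraph::is_dag(g)) stop("GO is_a edge graph contains a cycle")
  }
  tab
}
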