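# Generics and accessors. Slot access from user code should go through
# these rather than @.

#' @rdname TranscriptSet-class
#' @param x,object A \code{TranscriptSet}.
#' @export
setGeneric("transcriptIds", function(x) standardGeneric("transcriptIds"))

#' @rdname TranscriptSet-class
#' @export
setMethod("transcriptIds", "TranscriptSet", function(x) names(x@seqs))

#' @rdname TranscriptSet-class
#' @export
setGeneric("transcriptSeqs", function(x) standardGeneric("transcriptSeqs"))

#' @rdname TranscriptSet-class
#' @export
setMethod("transcriptSeqs", "TranscriptSet", function(x) x@seqs)

#' @rdname TranscriptSet-class
#' @export
setGeneric("speciesTag", function(x) standardGeneric("speciesTag"))

#' @rdname TranscriptSet-class
#' @export
setMethod("speciesTag", "TranscriptSet", function(x) x@species)

#' @rdname TranscriptSet-class
#' @export
setGeneric("codingAnnotation", function(x) standardGeneric("codingAnnotation"))

#' @rdname TranscriptSet-class
#' @export
setMethod("codingAnnotation", "TranscriptSet", function(x) x@annotation)

#' @rdname TranscriptSet-class
#' @export
setGeneric("codingAnnotation<-",
           function(x, value) standardGeneric("codingAnnotation<-"))

#' @rdname TranscriptSet-class
#' @param value Replacement annotation \code{data.frame}.
#' @export
setMethod("codingAnnotation<-", "TranscriptSet", function(x, value) {
  x@annotation <- value
  validObject(x)
  x
})

setMethod("show", "TranscriptSet", function(object) {
  cat("TranscriptSet of", length(object@seqs), "transcripts, species",
      sQuote(object@species), "\n")
  cat("  annotated:", length(unique(object@annotation$transcript_id)),
      "\n")
})

#' @rdname CodonAlignment-class
#' @param x,object A \code{CodonAlignment}.
#' @export
setGeneric("alignedCodons", function(x) standardGeneric("alignedCodons"))

#' @rdname CodonAlignment-class
#' @export
setMethod("alignedCodons", "CodonAlignment",
          function(x) list(a = .splitCodons(x@alnA),
                           b = .splitCodons(x@alnB)))

#' @rdname CodonAlignment-class
#' @export
setGeneric("comparedCodons", function(x) standardGeneric("comparedCodons"))

#' @rdname CodonAlignment-class
#' @export
setMethod("comparedCodons", "CodonAlignment",
          function(x) x@comparedCodons)

#' @rdname CodonAlignment-class
#' @export
setGeneric("qcStatus", function(x) standardGeneric("qcStatus"))

#' @rdname CodonAlignment-class
#' @export
setMethod("qcStatus", "CodonAlignment", function(x)
  if (x@status == "pass") "pass" else paste0("fail(", x@reason, ")"))

#' @rdname CodonAlignment-class
#' @export
setGeneric("pairId", function(x) standardGeneric("pairId"))

#' @rdname CodonAlignment-class
#' @export
setMethod("pairId", "CodonAlignment", function(x) x@pairId)

#' @rdname KaKsResult-class
#' @export
setMethod("pairId", "KaKsResult", function(x) x@pairId)

setMethod("show", "CodonAlignment", function(object) {
  cat("CodonAlignment", sQuote(object@pairId), "-",
      nchar(object@alnA) / 3, "columns,",
      object@comparedCodons, "compared,", qcStatus(object), "\n")
})

setMethod("show", "KaKsResult", function(object) {
  cat("KaKsResult", sQuote(object@pairId),
      sprintf("[%s]", object@method), "\n")
  cat(sprintf("  S = %.2f  N = %.2f  Sd = %.3f  Nd = %.3f  kappa = %.3f\n",
              object@S, object@N, object@Sd, object@Nd, object@kappa))
  cat(sprintf("  Ka = %s  Ks = %s  Ka/Ks = %s  bucket = %s\n",
              format(object@Ka, digits = 4),
              format(object@Ks, digits = 4),
              format(object@ratio, digits = 4), object@bucket))
  if (length(object@warnings))
    cat("  warnings:", paste(object@warnings, collapse = "; "), "\n")
})

setMethod("show", "ScreenReport", function(object) {
  cat("ScreenReport:", nrow(object@results), "pairs analysed\n")
  cnt <- object@counts
  cat(sprintf("  RBH pairs: %d  redundancy-collapsed: %d  QC-failed: %d\n",
              cnt$n_rbh, cnt$n_collapsed, sum(unlist(cnt$qc_fail))))
  cat(sprintf("  Ks-filtered paralogs: %d\n", cnt$n_paralog_filtered))
  b <- cnt$buckets
  cat(sprintf("  buckets: %d identical / %d one-type / %d both\n",
              b[["identical"]], b[["syn_only"]] + b[["nonsyn_only"]],
              b[["both"]]))
  k <- cnt$classes
  cat(sprintf("  classes: %d strong / %d candidate / %d non-candidate\n",
              k[["strong"]], k[["candidate"]], k[["non_candidate"]]))
})

#' Extract a KaKsResult as a one-row data.frame
#'
#' @param x A \code{KaKsResult}.
#' @return One-row \code{data.frame} with the slots as columns.
#' @export
setGeneric("asRow", function(x) standardGeneric("asRow"))

#' @rdname asRow
#' @export
setMethod("asRow", "KaKsResult", function(x) {
  data.frame(pair_id = x@pairId, method = x@method, S = x@S, N = x@N,
             Sd = x@Sd, Nd = x@Nd, kappa = x@kappa, Ka = x@Ka, Ks = x@Ks,
             ratio = x@ratio, bucket = x@bucket,
             excluded_columns = x@excludedColumns,
             warnings = paste(x@warnings, collapse = ";"),
             stringsAsFactors = FALSE)
})
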