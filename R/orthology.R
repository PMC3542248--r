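# Putative one-to-one ortholog identification between two species:
# exhaustive six-frame x six-frame local protein alignment (BLOSUM62,
# affine gaps) in place of a seeded translated BLAST, reciprocal best
# hits, and collapse of splice-variant redundancy.
#
# Raw Smith-Waterman scores are converted to bit scores with fixed gapped
# Karlin-Altschul constants (lambda = 0.267, K = 0.041, the standard
# gapped BLOSUM62 values), so the familiar bit-score-300 threshold applies
# unchanged. "Best hit" means the highest single local alignment bit
# score, not an HSP sum.

.SW_LAMBDA <- 0.267
.SW_K <- 0.041
.FRAME_LABELS <- c(1L, 2L, 3L, -1L, -2L, -3L)

#' @noRd
.blosum62 <- function() {
  if (is.null(.kaks_cache$blosum62)) {
    e <- new.env()
    data("BLOSUM62", package = "Biostrings", envir = e)
    .kaks_cache$blosum62 <- e$BLOSUM62
  }
  .kaks_cache$blosum62
}

# integer-code the six frame translations of a DNAStringSet for the C
# kernel: one concatenated vector plus per-slot offset/length (6 slots per
# transcript, frames +1,+2,+3,-1,-2,-3)
#' @noRd
.frameCodes <- function(seqs) {
  alpha <- rownames(.blosum62())
  xIdx <- match("X", alpha)
  n <- length(seqs)
  L <- width(seqs)
  rc <- Biostrings::reverseComplement(seqs)
  aaByFrame <- vector("list", 6L)
  for (f in 1:6) {
    src <- if (f <= 3) seqs else rc
    off <- (f - 1L) %% 3L
    start <- pmin(off + 1L, L + 1L)
    end <- off + ((L - off) %/% 3L) * 3L
    end <- pmax(end, start - 1L)
    sub <- Biostrings::subseq(src, start = start, end = end)
    aaByFrame[[f]] <- suppressWarnings(
      as.character(Biostrings::translate(sub, if.fuzzy.codon = "X")))
  }
  seqv <- integer(0)
  offv <- integer(n * 6L)
  lenv <- integer(n * 6L)
  chunks <- vector("list", n * 6L)
  for (i in seq_len(n)) {
    for (f in 1:6) {
      slot <- (i - 1L) * 6L + f
      s <- aaByFrame[[f]][i]
      if (nzchar(s)) {
        v <- match(strsplit(s, "", fixed = TRUE)[[1]], alpha)
        v[is.na(v)] <- xIdx
        chunks[[slot]] <- v - 1L
        lenv[slot] <- length(v)
      } else lenv[slot] <- 0L
    }
  }
  lens <- vapply(chunks, function(x) if (is.null(x)) 0L else length(x),
                 integer(1))
  offv <- cumsum(c(0L, lens[-length(lens)]))
  seqv <- unlist(chunks, use.names = FALSE)
  if (is.null(seqv)) seqv <- integer(0)
  list(seq = seqv, off = as.integer(offv), len = lenv, codes = chunks)
}

#' Convert a raw local-alignment score to bits
#'
#' Uses the gapped Karlin-Altschul constants declared for the search
#' (\code{lambda} = 0.267, \code{K} = 0.041 by default):
#' \code{bits = (lambda * raw - ln K) / ln 2}.
#'
#' @param raw Raw alignment score(s).
#' @param lambda,K Karlin-Altschul parameters.
#' @return Bit score(s).
#' @export
bitScore <- function(raw, lambda = .SW_LAMBDA, K = .SW_K) {
  (lambda * raw - log(K)) / log(2)
}

#' Six-frame translated similarity search between two transcript sets
#'
#' For each query-subject transcript pair, computes the best local protein
#' alignment (Smith-Waterman, BLOSUM62, affine gaps) over all 36 frame
#' combinations, keeps the best hit per pair, and drops hits whose bit
#' score falls below \code{bitThreshold}. A transcript never hits itself
#' when the same set is used on both sides.
#'
#' @param queries,subjects \code{TranscriptSet}s (both nonempty).
#' @param bitThreshold Minimum bit score retained (default 300).
#' @param gapOpen,gapExt Affine gap penalties (opening a gap of length L
#'   costs \code{gapOpen + L * gapExt}).
#' @param lambda,K Karlin-Altschul constants for the bit conversion.
#' @return \code{data.frame} with columns \code{query_id},
#'   \code{subject_id}, \code{query_frame}, \code{subject_frame},
#'   \code{raw_score}, \code{bit_score}, \code{aligned_length} (alignment
#'   columns, amino acids) and \code{identity_fraction}.
#' @export
translatedSearch <- function(queries, subjects, bitThreshold = 300,
                             gapOpen = 10, gapExt = 1,
                             lambda = .SW_LAMBDA, K = .SW_K) {
  stopifnot(is(queries, "TranscriptSet"), is(subjects, "TranscriptSet"))
  if (length(transcriptSeqs(queries)) == 0L ||
      length(transcriptSeqs(subjects)) == 0L)
    stop("both transcript sets must be nonempty")
  qc <- .frameCodes(transcriptSeqs(queries))
  sc <- .frameCodes(transcriptSeqs(subjects))
  sub <- .blosum62()
  minRaw <- (bitThreshold * log(2) + log(K)) / lambda
  hits <- .sw_best_hits(qc$seq, qc$off, qc$len, sc$seq, sc$off, sc$len,
                        length(transcriptSeqs(queries)),
                        length(transcriptSeqs(subjects)),
                        transcriptIds(queries), transcriptIds(subjects),
                        sub, as.integer(gapOpen), as.integer(gapExt),
                        minRaw)
  n <- nrow(hits)
  alen <- integer(n)
  ident <- numeric(n)
  for (r in seq_len(n)) {
    qslot <- (hits$qi[r] - 1L) * 6L + hits$qframe[r]
    sslot <- (hits$si[r] - 1L) * 6L + hits$sframe[r]
    st <- .sw_align_stats(qc$codes[[qslot]], sc$codes[[sslot]], sub,
                          as.integer(gapOpen), as.integer(gapExt))
    alen[r] <- st[["columns"]]
    ident[r] <- if (st[["columns"]] > 0) st[["matches"]] / st[["columns"]] else 0
  }
  out <- data.frame(
    query_id = transcriptIds(queries)[hits$qi],
    subject_id = transcriptIds(subjects)[hits$si],
    query_frame = .FRAME_LABELS[hits$qframe],
    subject_frame = .FRAME_LABELS[hits$sframe],
    raw_score = hits$raw,
    bit_score = bitScore(hits$raw, lambda, K),
    aligned_length = alen,
    identity_fraction = ident,
    stringsAsFactors = FALSE)
  out[out$bit_score >= bitThreshold, , drop = FALSE]
}

# best subject per query under the tie rule: higher bit, then higher
# identity, then lexicographically smaller subject id
#' @noRd
.bestHits <- function(hits, queryCol = "query_id",
                      subjectCol = "subject_id") {
  if (nrow(hits) == 0L) return(hits[0, , drop = FALSE])
  o <- order(hits[[queryCol]], -hits$bit_score, -hits$identity_fraction,
             hits[[subjectCol]])
  h <- hits[o, , drop = FALSE]
  h[!duplicated(h[[queryCol]]), , drop = FALSE]
}

#' Reciprocal best hits from two directional hit tables
#'
#' A pair \code{(a, b)} is emitted iff \code{b} is \code{a}'s unique best
#' subject in \code{hitsAB} and \code{a} is \code{b}'s unique best subject
#' in \code{hitsBA}. Bit-score ties are broken by higher identity
#' fraction, then lexicographically smaller subject id, making the best
#' hit unique. Each transcript occurs in at most one pair.
#'
#' @param hitsAB,hitsBA Hit tables from [translatedSearch()] run in the
#'   two directions.
#' @return \code{data.frame} with columns \code{id_a}, \code{id_b},
#'   \code{bit_ab}, \code{bit_ba}.
#' @export
reciprocalBestHits <- function(hitsAB, hitsBA) {
  empty <- data.frame(id_a = character(), id_b = character(),
                      bit_ab = numeric(), bit_ba = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(hitsAB) == 0L || nrow(hitsBA) == 0L) return(empty)
  bestAB <- .bestHits(hitsAB)
  bestBA <- .bestHits(hitsBA)
  key <- paste(bestAB$query_id, bestAB$subject_id, sep = "\r")
  rev <- paste(bestBA$subject_id, bestBA$query_id, sep = "\r")
  keep <- key %in% rev
  if (!any(keep)) return(empty)
  out <- data.frame(id_a = bestAB$query_id[keep],
                    id_b = bestAB$subject_id[keep],
                    bit_ab = bestAB$bit_score[keep],
                    stringsAsFactors = FALSE)
  out$bit_ba <- bestBA$bit_score[match(paste(out$id_b, out$id_a,
                                             sep = "\r"),
                                       paste(bestBA$query_id,
                                             bestBA$subject_id,
                                             sep = "\r"))]
  out[order(out$id_a), , drop = FALSE]
}

#' Attach coding sequences and reference-gene labels to RBH pairs
#'
#' Annotated transcripts contribute their annotated CDS; unannotated ones
#' their longest predicted ORF (strictly longer than \code{minOrfNt}).
#' A pair is \code{annotated} when both members carry annotation,
#' \code{orf_predicted} otherwise. Pairs where a CDS cannot be obtained
#' are dropped (tallied in attribute \code{"dropped"}).
#'
#' @param rbh Output of [reciprocalBestHits()].
#' @param tsA,tsB The two species' \code{TranscriptSet}s.
#' @param minOrfNt ORF length threshold for unannotated members.
#' @return \code{data.frame} with columns \code{id_a}, \code{id_b},
#'   \code{ref_gene_id}, \code{cds_a}, \code{cds_b}, \code{source},
#'   \code{ref_start}, \code{ref_end}.
#' @export
buildOrthologPairs <- function(rbh, tsA, tsB, minOrfNt = 300) {
  annA <- codingAnnotation(tsA); annB <- codingAnnotation(tsB)
  hasRef <- all(c("ref_start", "ref_end") %in% names(annA))
  rows <- vector("list", nrow(rbh))
  dropped <- 0L
  for (i in seq_len(nrow(rbh))) {
    ida <- rbh$id_a[i]; idb <- rbh$id_b[i]
    ra <- annA[annA$transcript_id == ida, , drop = FALSE]
    rb <- annB[annB$transcript_id == idb, , drop = FALSE]
    annotated <- nrow(ra) > 0L && nrow(rb) > 0L
    cdsA <- if (nrow(ra)) extractAnnotatedCds(tsA, ida)
            else { o <- longestOrf(setNames(
                     as.character(transcriptSeqs(tsA)[[ida]]), ida),
                     minOrfNt); if (is.null(o)) NA_character_ else o$cds }
    cdsB <- if (nrow(rb)) extractAnnotatedCds(tsB, idb)
            else { o <- longestOrf(setNames(
                     as.character(transcriptSeqs(tsB)[[idb]]), idb),
                     minOrfNt); if (is.null(o)) NA_character_ else o$cds }
    if (is.na(cdsA) || is.na(cdsB) || !nzchar(cdsA) || !nzchar(cdsB)) {
      dropped <- dropped + 1L
      next
    }
    gene <- if (nrow(ra)) ra$ref_gene_id[1]
            else if (nrow(rb)) rb$ref_gene_id[1] else NA_character_
    refRow <- if (nrow(ra)) ra[1, ] else if (nrow(rb)) rb[1, ] else NULL
    rs <- re <- NA_real_
    if (!is.null(refRow)) {
      if (hasRef && !is.na(refRow$ref_start)) {
        rs <- refRow$ref_start; re <- refRow$ref_end
      } else {
        rs <- refRow$coding_start; re <- refRow$coding_end
      }
    }
    rows[[i]] <- data.frame(
      id_a = ida, id_b = idb, ref_gene_id = gene,
      cds_a = cdsA, cds_b = cdsB,
      source = if (annotated) "annotated" else "orf_predicted",
      ref_start = rs, ref_end = re, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(id_a = character(), id_b = character(),
                      ref_gene_id = character(), cds_a = character(),
                      cds_b = character(), source = character(),
                      ref_start = numeric(), ref_end = numeric(),
                      stringsAsFactors = FALSE)
  attr(out, "dropped") <- dropped
  out
}

#' Collapse splice-variant redundancy among ortholog pairs
#'
#' Among pairs that match the same reference gene and whose annotated
#' regions overlap on the reference, only the pair with the largest total
#' CDS length (\code{cds_a} plus \code{cds_b}) is retained, so the output
#' represents unique genes. Pairs on different genes, pairs without a
#' reference gene, and same-gene pairs with disjoint annotated regions are
#' untouched.
#'
#' @param pairs Output of [buildOrthologPairs()].
#' @return The retained pairs; removed rows are recorded in attribute
#'   \code{"removed"}.
#' @export
collapseRedundant <- function(pairs) {
  if (nrow(pairs) == 0L) {
    attr(pairs, "removed") <- pairs
    return(pairs)
  }
  keep <- rep(TRUE, nrow(pairs))
  hasGene <- !is.na(pairs$ref_gene_id) & !is.na(pairs$ref_start)
  for (g in unique(pairs$ref_gene_id[hasGene])) {
    idx <- which(hasGene & pairs$ref_gene_id == g)
    if (length(idx) < 2L) next
    ir <- IRanges::IRanges(start = as.integer(pairs$ref_start[idx]) + 1L,
                           end = as.integer(pairs$ref_end[idx]))
    # connected components of the interval-overlap graph
    ov <- IRanges::findOverlaps(ir, ir)
    g2 <- igraph::graph_from_data_frame(
      data.frame(from = S4Vectors::queryHits(ov),
                 to = S4Vectors::subjectHits(ov)),
      directed = FALSE,
      vertices = data.frame(name = seq_along(idx)))
    comp <- igraph::components(g2)$membership
    total <- nchar(pairs$cds_a[idx]) + nchar(pairs$cds_b[idx])
    for (cc in unique(comp)) {
      members <- idx[comp == cc]
      if (length(members) < 2L) next
      best <- members[order(-total[comp == cc], pairs$id_a[members])][1]
      keep[setdiff(members, best)] <- FALSE
    }
  }
  out <- pairs[keep, , drop = FALSE]
  attr(out, "removed") <- pairs[!keep, , drop = FALSE]
  out
}
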