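# End-to-end orchestration: ORF/annotation CDS extraction, translated
# RBH orthology, redundancy collapse, codon alignment QC, Ka/Ks
# estimation, Ks paralog filtering, candidate classification and GO-level
# screening, with stage-by-stage accounting in the style of the source
# screen (identical / one-type-only / both buckets, QC failures by
# reason, paralogs removed).

#' Configuration for a screen run
#'
#' Collects input paths (or in-memory objects) and every threshold the
#' pipeline applies. The configuration is echoed verbatim into the
#' report.
#'
#' @param fastaA,fastaB FASTA paths, or \code{TranscriptSet}s.
#' @param speciesA,speciesB Species tags (used when reading FASTA).
#' @param annotationFile Optional annotation TSV path (or a
#'   \code{data.frame}) applying to both species' transcripts.
#' @param goAnnotationFile Optional gene-to-term TSV path or
#'   \code{data.frame}.
#' @param goEdgeFile Optional GO edge TSV path or \code{data.frame}.
#' @param step1Terms,step2Terms A-priori screen term id vectors.
#' @param bitThreshold Bit-score threshold of the translated search.
#' @param minCdsAnnotated,minCdsOrf Alignment length QC in nt.
#' @param minOrfNt ORF prediction threshold (strict) for unannotated
#'   transcripts.
#' @param ksMax Ks paralog-exclusion threshold.
#' @param candidateCut,strongCut Ka/Ks classification thresholds.
#' @param goMinN Minimum orthologs per reported GO term.
#' @param goLevel Level for the category-distribution rollup.
#' @param method \code{"YN"} or \code{"NG86"}.
#' @param seed Seed applied before any stochastic stage.
#' @param outDir Optional directory; when set, stage artifacts are
#'   written there as TSV.
#' @return Config list of class \code{ScreenConfig}.
#' @export
screenConfig <- function(fastaA, fastaB, speciesA = "speciesA",
                         speciesB = "speciesB", annotationFile = NULL,
                         goAnnotationFile = NULL, goEdgeFile = NULL,
                         step1Terms = defaultScreenTerms("hypoxia"),
                         step2Terms = defaultScreenTerms("poikilotherm"),
                         bitThreshold = 300, minCdsAnnotated = 200,
                         minCdsOrf = 300, minOrfNt = 300, ksMax = 0.1,
                         candidateCut = 0.5, strongCut = 1,
                         goMinN = 10, goLevel = 3,
                         method = c("YN", "NG86"), seed = 1,
                         outDir = NULL) {
  method <- match.arg(method)
  stopifnot(bitThreshold > 0, minCdsAnnotated > 0, minCdsOrf > 0,
            minOrfNt > 0, ksMax > 0, candidateCut > 0,
            strongCut > candidateCut, goMinN > 0, goLevel > 0)
  structure(as.list(environment()), class = "ScreenConfig")
}

#' @noRd
.loadInputs <- function(config) {
  loadTs <- function(x, species, label) {
    if (is(x, "TranscriptSet")) return(x)
    tryCatch(readTranscripts(x, species),
             error = function(e)
               stop("stage input [", label, "]: ", conditionMessage(e),
                    call. = FALSE))
  }
  tsA <- loadTs(config$fastaA, config$speciesA, "species A FASTA")
  tsB <- loadTs(config$fastaB, config$speciesB, "species B FASTA")
  if (!is.null(config$annotationFile)) {
    ann <- if (is.data.frame(config$annotationFile)) config$annotationFile
           else readAnnotationTable(config$annotationFile)
    annFor <- function(ts) {
      keep <- ann$transcript_id %in% transcriptIds(ts)
      ann[keep, , drop = FALSE]
    }
    suppressWarnings({
      codingAnnotation(tsA) <- annFor(tsA)
      codingAnnotation(tsB) <- annFor(tsB)
    })
  }
  loadTab <- function(x, reader) {
    if (is.null(x)) return(NULL)
    if (is.data.frame(x)) x else reader(x)
  }
  list(tsA = tsA, tsB = tsB,
       goAnnotation = loadTab(config$goAnnotationFile, readGOAnnotations),
       goEdges = loadTab(config$goEdgeFile, readGOEdges))
}

#' Run the full positive-selection screen
#'
#' Executes translated RBH orthology, CDS extraction
#' (annotation-guided or ORF-predicted), redundancy collapse, codon
#' alignment with QC, Ka/Ks estimation, Ks paralog filtering, Ka/Ks
#' classification, and — when GO tables are supplied — term-mean
#' aggregation, level-3 category distribution and the two-step a-priori
#' screen.
#'
#' @param config A [screenConfig()].
#' @return A [ScreenReport-class].
#' @export
runScreen <- function(config) {
  stopifnot(inherits(config, "ScreenConfig"))
  set.seed(config$seed)
  inp <- .loadInputs(config)
  tsA <- inp$tsA; tsB <- inp$tsB
  counts <- list(n_transcripts_a = length(transcriptSeqs(tsA)),
                 n_transcripts_b = length(transcriptSeqs(tsB)))

  message("stage: translated search (", counts$n_transcripts_a, " x ",
          counts$n_transcripts_b, " transcripts)")
  hitsAB <- translatedSearch(tsA, tsB, bitThreshold = config$bitThreshold)
  # local alignment scores are symmetric: derive the reverse direction
  hitsBA <- data.frame(query_id = hitsAB$subject_id,
                       subject_id = hitsAB$query_id,
                       query_frame = hitsAB$subject_frame,
                       subject_frame = hitsAB$query_frame,
                       raw_score = hitsAB$raw_score,
                       bit_score = hitsAB$bit_score,
                       aligned_length = hitsAB$aligned_length,
                       identity_fraction = hitsAB$identity_fraction,
                       stringsAsFactors = FALSE)
  counts$n_hits <- nrow(hitsAB)

  message("stage: reciprocal best hits")
  rbh <- reciprocalBestHits(hitsAB, hitsBA)
  counts$n_rbh <- nrow(rbh)

  message("stage: CDS extraction")
  pairs <- buildOrthologPairs(rbh, tsA, tsB, minOrfNt = config$minOrfNt)
  counts$n_cds_dropped <- attr(pairs, "dropped")
  counts$n_pairs_with_cds <- nrow(pairs)

  message("stage: redundancy collapse")
  pairs <- collapseRedundant(pairs)
  counts$n_collapsed <- nrow(attr(pairs, "removed"))
  counts$n_unique_pairs <- nrow(pairs)
  collapsedPairs <- attr(pairs, "removed")
  counts$collapsed_ids <- c(collapsedPairs$id_a, collapsedPairs$id_b)

  message("stage: codon alignment + QC (", nrow(pairs), " pairs)")
  qcFail <- c(stop_codon = 0L, ambiguous = 0L, too_short = 0L)
  alignments <- list()
  kept <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    pid <- paste(pairs$id_a[i], pairs$id_b[i], sep = "|")
    aln <- alignCodonPair(pairs$cds_a[i], pairs$cds_b[i],
                          pairIdent = pid)
    aln <- qcFilter(aln, pairs$source[i],
                    minNtAnnotated = config$minCdsAnnotated,
                    minNtOrf = config$minCdsOrf)
    if (aln@status == "pass") {
      alignments[[pid]] <- aln
      kept[i] <- TRUE
    } else {
      qcFail[aln@reason] <- qcFail[aln@reason] + 1L
    }
  }
  counts$qc_fail <- as.list(qcFail)
  counts$n_qc_pass <- sum(kept)
  pairs <- pairs[kept, , drop = FALSE]

  message("stage: Ka/Ks (", length(alignments), " alignments, ",
          config$method, ")")
  results <- kaksTable(alignments, method = config$method)
  results$id_a <- pairs$id_a[match(results$pair_id,
                                   paste(pairs$id_a, pairs$id_b,
                                         sep = "|"))]
  results$id_b <- pairs$id_b[match(results$pair_id,
                                   paste(pairs$id_a, pairs$id_b,
                                         sep = "|"))]
  results$ref_gene_id <- pairs$ref_gene_id[match(
    results$pair_id, paste(pairs$id_a, pairs$id_b, sep = "|"))]
  results$source <- pairs$source[match(
    results$pair_id, paste(pairs$id_a, pairs$id_b, sep = "|"))]

  message("stage: paralog filter (Ks > ", config$ksMax, ")")
  results <- filterParalogs(results, ksMax = config$ksMax)
  paralogRemoved <- attr(results, "removed")
  counts$n_paralog_filtered <- nrow(paralogRemoved)
  counts$paralog_removed_ids <- paralogRemoved$pair_id
  counts$n_final <- nrow(results)

  results$class <- classifyCandidate(results$ratio,
                                     strongCut = config$strongCut,
                                     candidateCut = config$candidateCut)
  counts$buckets <- as.list(bucketCounts(results))
  clv <- c("strong", "candidate", "non_candidate", "unclassifiable")
  counts$classes <- as.list(setNames(
    as.integer(table(factor(results$class, levels = clv))), clv))

  termSummary <- data.frame()
  catDist <- data.frame()
  screenHits <- data.frame()
  if (!is.null(inp$goAnnotation)) {
    message("stage: GO aggregation")
    termSummary <- termMeanRatio(results, inp$goAnnotation,
                                 minN = config$goMinN)
    if (!is.null(inp$goEdges)) {
      catDist <- categoryDistribution(results, inp$goAnnotation,
                                      inp$goEdges,
                                      level = config$goLevel)
      screenHits <- functionalScreen(results, inp$goAnnotation,
                                     step1Terms = config$step1Terms,
                                     step2Terms = config$step2Terms,
                                     edges = inp$goEdges)
    }
    counts$n_screen_hits <- nrow(screenHits)
  }

  report <- new("ScreenReport", results = results, counts = counts,
                termSummary = termSummary,
                categoryDistribution = catDist,
                screenHits = screenHits,
                config = unclass(config))

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, f) write.table(
      x, file.path(config$outDir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    wt(hitsAB, "hits.tsv")
    wt(rbh, "rbh_pairs.tsv")
    wt(collapsedPairs[, setdiff(names(collapsedPairs),
                                c("cds_a", "cds_b"))],
       "collapsed_pairs.tsv")
    wt(paralogRemoved, "paralog_filtered.tsv")
    wt(results, "kaks_results.tsv")
    if (nrow(termSummary)) wt(termSummary, "term_summary.tsv")
    if (nrow(catDist)) wt(catDist, "category_distribution.tsv")
    if (nrow(screenHits)) wt(screenHits, "screen_hits.tsv")
  }
  report
}

#' Generate fixture artifacts from a specification
#'
#' Thin wrapper over [generateFixture()] + [writeFixture()]: validates
#' the spec, generates the fixture, and writes the FASTA/TSV artifacts.
#' Nothing is written if the spec is invalid.
#'
#' @param spec A [fixtureSpec()].
#' @param dir Output directory.
#' @return Named vector of the files written (invisibly the fixture as
#'   attribute \code{"fixture"}).
#' @export
runSimulate <- function(spec, dir) {
  fixture <- generateFixture(spec)
  files <- writeFixture(fixture, dir)
  attr(files, "fixture") <- fixture
  files
}

#' Accessors for ScreenReport
#' @param x A \code{ScreenReport}.
#' @return \code{screenResults}: the per-pair results \code{data.frame};
#'   \code{screenCounts}: the stage-accounting list.
#' @export
screenResults <- function(x) x@results

#' @rdname screenResults
#' @export
screenCounts <- function(x) x@counts
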