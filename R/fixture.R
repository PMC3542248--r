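# Transcriptome-scale fixture generation: ortholog pairs with known
# omega/kappa/divergence embedded in transcripts with UTRs, plus the
# confounders the screen must reject — paralog-like pairs with elevated
# Ks, splice-variant redundancy, and noncoding decoys — together with
# annotation, GO tables and a truth table covering every record.

#' Specification of a synthetic two-species transcriptome
#'
#' Defaults describe the screen's validation conditions: 200 ortholog
#' pairs of 200 codons, 10 of them evolved at omega = 2 with enough
#' divergence for tens of substitutions per pair, background pairs under
#' strong purifying selection tuned to Ks of about 0.04, 10 paralog-like
#' decoy pairs tuned to Ks of about 0.2 (above the 0.1 exclusion), 5
#' genes with an exon-skipped splice variant in both species, 20
#' noncoding transcripts, and 50 nt UTRs seeded with stop codons in all
#' frames so they never extend an open reading frame far.
#'
#' @param nOrthologPairs Total ortholog pairs (background + strong).
#' @param nStrong How many pairs evolve at \code{omegaStrong}.
#' @param omegaBackground,omegaStrong The two omega values.
#' @param kappa Transition/transversion ratio for all pairs.
#' @param nCodons Codons per coding sequence.
#' @param targetKsBackground Expected Ks of background (and variant)
#'   pairs; branch length is tuned to it.
#' @param tStrong Branch length of strong pairs (substitutions per codon
#'   along the full path).
#' @param nParalogDecoys Decoy pairs tuned to \code{paralogTargetKs};
#'   each is re-simulated until its realized truth Ks exceeds the 0.1
#'   exclusion threshold.
#' @param paralogTargetKs Must exceed \code{targetKsBackground} and 0.1.
#' @param nSpliceVariants Genes receiving one exon-skipped variant
#'   transcript per species.
#' @param skipCodons Codons removed in a splice variant.
#' @param nNoncoding Total noncoding transcripts, split evenly across the
#'   two species.
#' @param nUnannotated Background pairs left without annotation rows, to
#'   exercise the ORF-prediction path.
#' @param utrLength UTR length (nt) on each side.
#' @param revFraction Fraction of transcripts stored reverse-complemented
#'   (annotation strand -1).
#' @param speciesA,speciesB Species tags.
#' @param seed Integer seed; all fixture randomness flows from it.
#' @return Validated list of class \code{FixtureSpec}.
#' @export
fixtureSpec <- function(nOrthologPairs = 200, nStrong = 10,
                        omegaBackground = 0.1, omegaStrong = 2,
                        kappa = 2, nCodons = 200,
                        targetKsBackground = 0.04, tStrong = 0.25,
                        nParalogDecoys = 10, paralogTargetKs = 0.2,
                        nSpliceVariants = 5, skipCodons = 40,
                        nNoncoding = 20, nUnannotated = 10,
                        utrLength = 50, revFraction = 0.2,
                        speciesA = "spA", speciesB = "spB", seed = 1) {
  stopifnot(nOrthologPairs >= 0, nStrong >= 0,
            nStrong <= nOrthologPairs,
            nParalogDecoys >= 0, nSpliceVariants >= 0, nNoncoding >= 0,
            nUnannotated >= 0, nCodons >= 40, utrLength >= 0)
  if (nSpliceVariants > nOrthologPairs - nStrong)
    stop("more splice variants than background genes")
  if (nUnannotated > nOrthologPairs - nStrong - nSpliceVariants)
    stop("too many unannotated pairs requested")
  if (nParalogDecoys > 0 && paralogTargetKs <= targetKsBackground)
    stop("paralog Ks target must exceed the ortholog Ks target")
  if (nParalogDecoys > 0 && paralogTargetKs <= 0.1)
    stop("paralog Ks target must exceed the 0.1 exclusion threshold")
  structure(as.list(environment()), class = "FixtureSpec")
}

# UTR with stop codons seeded in all frames of both strands: blocks of a
# stop triplet (TAA forward or TTA, whose reverse complement is TAA) plus
# 1-2 random nucleotides, so the stop phase drifts through all frames
#' @noRd
.randomUtr <- function(len) {
  if (len <= 0) return("")
  out <- character()
  total <- 0L
  while (total < len) {
    stopc <- sample(c("TAA", "TAG", "TGA", "TTA", "CTA", "TCA"), 1L)
    pad <- paste(sample(.BASES, sample(1:2, 1L), replace = TRUE),
                 collapse = "")
    out <- c(out, stopc, pad)
    total <- total + nchar(stopc) + nchar(pad)
  }
  substr(paste(out, collapse = ""), 1L, len)
}

#' @noRd
.randomNoncoding <- function(len, maxOrfNt = 300) {
  for (try in 1:50) {
    s <- paste(sample(.BASES, len, replace = TRUE), collapse = "")
    orfs <- findOrfs(setNames(s, "x"), minNt = maxOrfNt)
    if (nrow(orfs) == 0L) return(s)
  }
  # fall back to a stop-dense sequence, guaranteed free of long ORFs
  substr(paste(replicate(ceiling(len / 4), paste0(
    sample(c("TAA", "TTA"), 1L), sample(.BASES, 1L))), collapse = ""),
    1L, len)
}

# package a CDS into a transcript: UTRs, optional reverse-complement
# storage; returns sequence plus forward-strand coding coordinates
#' @noRd
.packageTranscript <- function(cds, utrLen, reverse) {
  u5 <- .randomUtr(utrLen)
  u3 <- .randomUtr(utrLen)
  fwd <- paste0(u5, cds, u3)
  start <- nchar(u5)
  end <- start + nchar(cds)
  if (!reverse)
    return(list(seq = fwd, start = start, end = end, strand = 1L))
  L <- nchar(fwd)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(fwd)))
  list(seq = rc, start = L - end, end = L - start, strand = -1L)
}

#' Generate a synthetic two-species transcriptome fixture
#'
#' @param spec A [fixtureSpec()].
#' @return List with \code{tsA}, \code{tsB} (annotated
#'   [TranscriptSet-class]s), \code{goAnnotation}, \code{goEdges}
#'   (\code{data.frame}s), and \code{truth} (one row per emitted
#'   transcript: id, species, gene, role, omega, t, realized event counts
#'   and truth-level Ka/Ks).
#' @seealso [writeFixture()] to emit the files, [runScreen()] to analyse
#'   them.
#' @export
generateFixture <- function(spec) {
  stopifnot(inherits(spec, "FixtureSpec"))
  set.seed(spec$seed)
  nBack <- spec$nOrthologPairs - spec$nStrong
  baseParams <- codonSimParams(omega = spec$omegaBackground,
                               kappa = spec$kappa, t = 0.1,
                               nCodons = spec$nCodons)
  backParams <- tuneBranchLength(baseParams, spec$targetKsBackground)
  strongParams <- codonSimParams(omega = spec$omegaStrong,
                                 kappa = spec$kappa, t = spec$tStrong,
                                 nCodons = spec$nCodons)
  paraParams <- tuneBranchLength(
    codonSimParams(omega = spec$omegaBackground, kappa = spec$kappa,
                   t = 0.1, nCodons = spec$nCodons),
    spec$paralogTargetKs)

  seqsA <- character(); seqsB <- character()
  annA <- list(); annB <- list()
  truth <- list()
  goRows <- list()
  onto <- toyOntology()
  backgroundTerms <- c("GO:0044238", "GO:0019538", "GO:0006412",
                       "GO:0016043", "GO:0005488", "GO:0003824",
                       "GO:0016491", "GO:0006950")
  screenTerms <- c("GO:0001666", "GO:0019825", "GO:0009411",
                   "GO:0006749", "GO:0006200", "GO:0006979")

  addTranscript <- function(id, species, gene, protein, pk,
                            role, params, tr) {
    if (species == spec$speciesA) {
      seqsA[[id]] <<- pk$seq
      if (!is.null(gene))
        annA[[length(annA) + 1L]] <<- data.frame(
          transcript_id = id, ref_gene_id = gene,
          ref_protein_id = protein, coding_start = pk$start,
          coding_end = pk$end, strand = pk$strand,
          ref_start = 0L, ref_end = spec$nCodons,
          stringsAsFactors = FALSE)
    } else {
      seqsB[[id]] <<- pk$seq
      if (!is.null(gene))
        annB[[length(annB) + 1L]] <<- data.frame(
          transcript_id = id, ref_gene_id = gene,
          ref_protein_id = protein, coding_start = pk$start,
          coding_end = pk$end, strand = pk$strand,
          ref_start = 0L, ref_end = spec$nCodons,
          stringsAsFactors = FALSE)
    }
    truth[[length(truth) + 1L]] <<- data.frame(
      transcript_id = id, species = species,
      gene_id = if (is.null(gene)) NA_character_ else gene,
      role = role,
      omega = if (is.null(params)) NA_real_ else params$omega,
      t = if (is.null(params)) NA_real_ else params$t,
      syn_events = if (is.null(tr)) NA_real_ else tr$syn_events,
      nonsyn_events = if (is.null(tr)) NA_real_ else tr$nonsyn_events,
      ks_true = if (is.null(tr)) NA_real_ else tr$ks_true,
      ka_true = if (is.null(tr)) NA_real_ else tr$ka_true,
      stringsAsFactors = FALSE)
  }

  geneCounter <- 0L
  makePair <- function(params, role, annotate = TRUE, prefix = "g") {
    geneCounter <<- geneCounter + 1L
    gene <- sprintf("%s%03d", prefix, geneCounter)
    sim <- simulateCodonPair(params)
    idA <- sprintf("%s_%s", spec$speciesA, gene)
    idB <- sprintf("%s_%s", spec$speciesB, gene)
    revA <- runif(1) < spec$revFraction
    revB <- runif(1) < spec$revFraction
    pkA <- .packageTranscript(sim$cdsA, spec$utrLength, revA)
    pkB <- .packageTranscript(sim$cdsB, spec$utrLength, revB)
    g <- if (annotate) gene else NULL
    addTranscript(idA, spec$speciesA, g, paste0("p_", gene),
                  pkA, role, params, sim$truth)
    addTranscript(idB, spec$speciesB, g, paste0("p_", gene),
                  pkB, role, params, sim$truth)
    list(gene = gene, sim = sim)
  }

  # background ortholog pairs (some unannotated), then strong pairs
  variantSources <- list()
  strongGenes <- character()
  for (k in seq_len(nBack)) {
    annotate <- k <= nBack - spec$nUnannotated  # last few unannotated
    p <- makePair(backParams, "ortholog", annotate = annotate)
    if (length(variantSources) < spec$nSpliceVariants && annotate &&
        k <= spec$nSpliceVariants)
      variantSources[[p$gene]] <- p$sim
    terms <- sample(backgroundTerms, sample(1:3, 1L))
    if (annotate)
      goRows[[length(goRows) + 1L]] <-
        data.frame(gene_id = p$gene, term_id = terms,
                   stringsAsFactors = FALSE)
  }
  for (k in seq_len(spec$nStrong)) {
    p <- makePair(strongParams, "strong_ortholog")
    strongGenes <- c(strongGenes, p$gene)
    terms <- c(screenTerms[1L + (k - 1L) %% length(screenTerms)],
               sample(backgroundTerms, 1L))
    goRows[[length(goRows) + 1L]] <-
      data.frame(gene_id = p$gene, term_id = terms,
                 stringsAsFactors = FALSE)
  }

  # paralog-like decoy pairs: re-simulate until realized Ks exceeds 0.1
  for (k in seq_len(spec$nParalogDecoys)) {
    for (try in 1:25) {
      sim <- simulateCodonPair(paraParams)
      if (!is.na(sim$truth$ks_true) && sim$truth$ks_true > 0.1) break
      if (try == 25)
        stop("could not reach the paralog Ks target; spec unattainable")
    }
    gene <- sprintf("par%03d", k)
    idA <- sprintf("%s_%s", spec$speciesA, gene)
    idB <- sprintf("%s_%s", spec$speciesB, gene)
    pkA <- .packageTranscript(sim$cdsA, spec$utrLength,
                              runif(1) < spec$revFraction)
    pkB <- .packageTranscript(sim$cdsB, spec$utrLength,
                              runif(1) < spec$revFraction)
    addTranscript(idA, spec$speciesA, gene, paste0("p_", gene),
                  pkA, "paralog_decoy", paraParams, sim$truth)
    addTranscript(idB, spec$speciesB, gene, paste0("p_", gene),
                  pkB, "paralog_decoy", paraParams, sim$truth)
    goRows[[length(goRows) + 1L]] <-
      data.frame(gene_id = gene,
                 term_id = sample(backgroundTerms, 1L),
                 stringsAsFactors = FALSE)
  }

  # splice variants: same pair with a skipped internal exon, both species
  skipFrom <- (spec$nCodons - spec$skipCodons) %/% 2L
  for (gene in names(variantSources)) {
    sim <- variantSources[[gene]]
    skip <- function(cds) {
      cod <- .splitCodons(cds)
      paste(cod[-(seq_len(spec$skipCodons) + skipFrom)], collapse = "")
    }
    for (side in c("A", "B")) {
      sp <- if (side == "A") spec$speciesA else spec$speciesB
      cds <- skip(if (side == "A") sim$cdsA else sim$cdsB)
      id <- sprintf("%s_%s_v2", sp, gene)
      pk <- .packageTranscript(cds, spec$utrLength,
                               runif(1) < spec$revFraction)
      # variant annotation: same gene, same reference span (overlapping)
      if (side == "A") {
        seqsA[[id]] <- pk$seq
        annA[[length(annA) + 1L]] <- data.frame(
          transcript_id = id, ref_gene_id = gene,
          ref_protein_id = paste0("p_", gene), coding_start = pk$start,
          coding_end = pk$end, strand = pk$strand,
          ref_start = 0L, ref_end = spec$nCodons,
          stringsAsFactors = FALSE)
      } else {
        seqsB[[id]] <- pk$seq
        annB[[length(annB) + 1L]] <- data.frame(
          transcript_id = id, ref_gene_id = gene,
          ref_protein_id = paste0("p_", gene), coding_start = pk$start,
          coding_end = pk$end, strand = pk$strand,
          ref_start = 0L, ref_end = spec$nCodons,
          stringsAsFactors = FALSE)
      }
      truth[[length(truth) + 1L]] <- data.frame(
        transcript_id = id, species = sp, gene_id = gene,
        role = "splice_variant", omega = spec$omegaBackground,
        t = backParams$t, syn_events = NA_real_,
        nonsyn_events = NA_real_, ks_true = NA_real_,
        ka_true = NA_real_, stringsAsFactors = FALSE)
    }
  }

  # noncoding decoys, split across the species
  nNcA <- ceiling(spec$nNoncoding / 2)
  for (k in seq_len(spec$nNoncoding)) {
    sp <- if (k <= nNcA) spec$speciesA else spec$speciesB
    id <- sprintf("%s_nc%03d", sp, k)
    s <- .randomNoncoding(spec$nCodons * 3L)
    if (sp == spec$speciesA) seqsA[[id]] <- s else seqsB[[id]] <- s
    truth[[length(truth) + 1L]] <- data.frame(
      transcript_id = id, species = sp, gene_id = NA_character_,
      role = "noncoding", omega = NA_real_, t = NA_real_,
      syn_events = NA_real_, nonsyn_events = NA_real_,
      ks_true = NA_real_, ka_true = NA_real_, stringsAsFactors = FALSE)
  }

  bindAnn <- function(lst) {
    if (!length(lst)) {
      a <- emptyAnnotation()
      a$ref_start <- integer()
      a$ref_end <- integer()
      return(a)
    }
    do.call(rbind, lst)
  }
  tsA <- new("TranscriptSet",
             seqs = Biostrings::DNAStringSet(unlist(seqsA)),
             species = spec$speciesA, annotation = bindAnn(annA))
  tsB <- new("TranscriptSet",
             seqs = Biostrings::DNAStringSet(unlist(seqsB)),
             species = spec$speciesB, annotation = bindAnn(annB))
  validObject(tsA); validObject(tsB)
  goAnnotation <- unique(do.call(rbind, goRows))
  list(tsA = tsA, tsB = tsB, goAnnotation = goAnnotation,
       goEdges = onto$edges, truth = do.call(rbind, truth),
       spec = spec, strongGenes = strongGenes)
}

#' Write a fixture to disk
#'
#' Emits \code{<species>.fasta} for each species plus
#' \code{annotation.tsv}, \code{go_annotation.tsv}, \code{go_edges.tsv}
#' and \code{truth.tsv}, with the generating parameters echoed to
#' \code{fixture_params.tsv}.
#'
#' @param fixture Output of [generateFixture()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written.
#' @export
writeFixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(speciesTag(fixture$tsA), ".fasta"))
  fb <- file.path(dir, paste0(speciesTag(fixture$tsB), ".fasta"))
  writeTranscripts(fixture$tsA, fa)
  writeTranscripts(fixture$tsB, fb)
  ann <- rbind(codingAnnotation(fixture$tsA), codingAnnotation(fixture$tsB))
  fAnn <- file.path(dir, "annotation.tsv")
  write.table(ann, fAnn, sep = "\t", quote = FALSE, row.names = FALSE)
  fGo <- file.path(dir, "go_annotation.tsv")
  write.table(fixture$goAnnotation, fGo, sep = "\t", quote = FALSE,
              row.names = FALSE)
  fEdge <- file.path(dir, "go_edges.tsv")
  write.table(fixture$goEdges, fEdge, sep = "\t", quote = FALSE,
              row.names = FALSE)
  fTruth <- file.path(dir, "truth.tsv")
  write.table(fixture$truth, fTruth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  par <- fixture$spec
  par$class <- NULL
  fPar <- file.path(dir, "fixture_params.tsv")
  write.table(data.frame(parameter = names(par),
                         value = vapply(par, function(x)
                           paste(format(x), collapse = ","),
                           character(1))),
              fPar, sep = "\t", quote = FALSE, row.names = FALSE)
  c(fastaA = fa, fastaB = fb, annotation = fAnn, goAnnotation = fGo,
    goEdges = fEdge, truth = fTruth, params = fPar)
}

#' A small Gene Ontology with known level structure
#'
#' Two namespaces (biological process rooted at GO:0008150, molecular
#' function at GO:0003674) with terms at known minimum is_a depths,
#' including the terms used by the default a-priori screen lists.
#'
#' @return List with \code{edges} (child, parent, relation, namespace)
#'   and \code{termNames} (named character vector).
#' @export
toyOntology <- function() {
  e <- function(child, parent, ns)
    data.frame(child = child, parent = parent, relation = "is_a",
               namespace = ns, stringsAsFactors = FALSE)
  bp <- "biological_process"; mf <- "molecular_function"
  edges <- rbind(
    e("GO:0008152", "GO:0008150", bp),  # metabolic process       (2)
    e("GO:0050896", "GO:0008150", bp),  # response to stimulus    (2)
    e("GO:0009987", "GO:0008150", bp),  # cellular process        (2)
    e("GO:0044238", "GO:0008152", bp),  # primary metabolic       (3)
    e("GO:0006749", "GO:0008152", bp),  # glutathione metabolic   (3)
    e("GO:0006200", "GO:0008152", bp),  # ATP catabolic           (3)
    e("GO:0006950", "GO:0050896", bp),  # response to stress      (3)
    e("GO:0016043", "GO:0009987", bp),  # component organization  (3)
    e("GO:0001666", "GO:0006950", bp),  # response to hypoxia     (4)
    e("GO:0009411", "GO:0006950", bp),  # response to UV          (4)
    e("GO:0006979", "GO:0006950", bp),  # oxidative stress        (4)
    e("GO:0007031", "GO:0016043", bp),  # peroxisome organization (4)
    e("GO:0019538", "GO:0044238", bp),  # protein metabolic       (4)
    e("GO:0006412", "GO:0019538", bp),  # translation             (5)
    e("GO:0030163", "GO:0019538", bp),  # protein catabolic       (5)
    e("GO:0005488", "GO:0003674", mf),  # binding                 (2)
    e("GO:0003824", "GO:0003674", mf),  # catalytic activity      (2)
    e("GO:0019825", "GO:0005488", mf),  # oxygen binding          (3)
    e("GO:0016491", "GO:0003824", mf))  # oxidoreductase          (3)
  termNames <- c(
    "GO:0008150" = "biological_process", "GO:0003674" = "molecular_function",
    "GO:0008152" = "metabolic process", "GO:0050896" = "response to stimulus",
    "GO:0009987" = "cellular process", "GO:0044238" = "primary metabolic process",
    "GO:0006749" = "glutathione metabolic process",
    "GO:0006200" = "ATP catabolic process", "GO:0006950" = "response to stress",
    "GO:0016043" = "cellular component organization",
    "GO:0001666" = "response to hypoxia", "GO:0009411" = "response to UV",
    "GO:0006979" = "response to oxidative stress",
    "GO:0007031" = "peroxisome organization",
    "GO:0019538" = "protein metabolic process", "GO:0006412" = "translation",
    "GO:0030163" = "protein catabolic process", "GO:0005488" = "binding",
    "GO:0003824" = "catalytic activity", "GO:0019825" = "oxygen binding",
    "GO:0016491" = "oxidoreductase activity")
  list(edges = edges, termNames = termNames)
}
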