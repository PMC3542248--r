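# ORF prediction: stop-to-stop maximality in all six frames, strict
# length threshold, tie rules, coordinate conventions.

# brute-force reference scanner: translate every frame with Biostrings
# and split on stops/ambiguity
referenceOrfs <- function(seq, minNt) {
  L <- nchar(seq)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq)))
  out <- list()
  for (fr in c(1, 2, 3, -1, -2, -3)) {
    s <- if (fr > 0) seq else rc
    off <- abs(fr) - 1
    n <- (L - off) %/% 3
    if (n < 1) next
    cods <- substring(s, off + 3 * seq_len(n) - 2, off + 3 * seq_len(n))
    isBrk <- grepl("N", cods) |
      cods %in% names(Biostrings::GENETIC_CODE)[
        Biostrings::GENETIC_CODE == "*"]
    run <- 0
    for (i in seq_len(n + 1)) {
      if (i <= n && !isBrk[i]) run <- run + 1
      else {
        if (run * 3 > minNt) {
          c0 <- i - run; c1 <- i - 1
          sS <- off + (c0 - 1) * 3; sE <- off + c1 * 3
          out[[length(out) + 1]] <- data.frame(
            frame = fr,
            start = if (fr > 0) sS else L - sE,
            end = if (fr > 0) sE else L - sS,
            nt_length = run * 3)
        }
        run <- 0
      }
    }
  }
  df <- do.call(rbind, out)
  if (is.null(df)) return(df)
  df[order(df$frame, df$start), ]
}

test_that("findOrfs matches a brute-force six-frame scan on random sequences", {
  set.seed(7)
  for (i in 1:10) {
    seq <- paste(sample(c("A", "C", "G", "T", "N"), 120, replace = TRUE,
                        prob = c(.24, .24, .24, .24, .04)),
                 collapse = "")
    got <- findOrfs(setNames(seq, "x"), minNt = 0)
    got <- got[order(got$frame, got$start),
               c("frame", "start", "end", "nt_length")]
    rownames(got) <- NULL
    ref <- referenceOrfs(seq, 0)
    rownames(ref) <- NULL
    expect_equal(got, ref)
  }
})

test_that("a poly-A transcript has a full-length frame +1 ORF and ties resolve by frame order", {
  seq <- paste(rep("A", 90), collapse = "")
  orfs <- findOrfs(setNames(seq, "x"), minNt = 0)
  f1 <- orfs[orfs$frame == 1, ]
  expect_equal(f1$start, 0)
  expect_equal(f1$end, 90)
  expect_equal(f1$nt_length, 90)
  # reverse frame -1 is poly-T (Phe), also 90 nt: the tie goes to +1
  best <- longestOrf(setNames(seq, "x"), minNt = 0)
  expect_equal(best$frame, 1)
})

test_that("the length threshold is strict: an ORF of exactly minNt is excluded", {
  cds <- paste(rep("AAA", 100), collapse = "")        # 300 nt, no stops
  seq <- paste0("TAA", cds, "TAA")
  at300 <- findOrfs(setNames(seq, "x"), minNt = 300)
  expect_false(any(at300$frame == 1 & at300$nt_length == 300))
  at299 <- findOrfs(setNames(seq, "x"), minNt = 299)
  expect_true(any(at299$frame == 1 & at299$nt_length == 300))
})

test_that("every reported ORF is maximal and stop-free", {
  set.seed(21)
  seq <- randomCds(80)  # coding-like, so long ORFs exist in several frames
  orfs <- findOrfs(setNames(seq, "x"), minNt = 0)
  stops <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == "*"]
  L <- nchar(seq)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq)))
  for (i in seq_len(nrow(orfs))) {
    o <- orfs[i, ]
    cods <- strsplit(o$cds, "")[[1]]
    cods <- substring(o$cds, seq(1, nchar(o$cds), 3),
                      seq(3, nchar(o$cds), 3))
    expect_false(any(cods %in% stops))
    # extension by one codon in either direction hits a stop, an N codon,
    # or the sequence boundary (checked on the scanned strand)
    s <- if (o$frame > 0) seq else rc
    sS <- if (o$frame > 0) o$start else L - o$end
    sE <- if (o$frame > 0) o$end else L - o$start
    if (sS - 3 >= 0) {
      prev <- substr(s, sS - 2, sS)
      expect_true(prev %in% stops || grepl("N", prev))
    }
    if (sE + 3 <= L) {
      nxt <- substr(s, sE + 1, sE + 3)
      expect_true(nxt %in% stops || grepl("N", nxt))
    }
  }
})

test_that("ORF coordinates mirror under reverse complement", {
  set.seed(33)
  seq <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
               collapse = "")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq)))
  fwd <- findOrfs(setNames(seq, "x"), minNt = 0)
  rev <- findOrfs(setNames(rc, "x"), minNt = 0)
  L <- nchar(seq)
  mirrored <- data.frame(frame = -fwd$frame,
                         start = L - fwd$end, end = L - fwd$start,
                         nt_length = fwd$nt_length)
  o1 <- mirrored[order(mirrored$frame, mirrored$start), ]
  o2 <- rev[order(rev$frame, rev$start),
            c("frame", "start", "end", "nt_length")]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o2, o1)
})

test_that("annotated CDS extraction follows the coordinate and frame rules", {
  ann <- data.frame(transcript_id = "t1", ref_gene_id = "g",
                    ref_protein_id = "p", coding_start = 0L,
                    coding_end = 12L, strand = 1L,
                    stringsAsFactors = FALSE)
  ts <- TranscriptSet(c(t1 = "ATGAAACCCGGGTT"), species = "s",
                      annotation = ann)
  expect_equal(extractAnnotatedCds(ts, "t1"), "ATGAAACCCGGG")

  ann$coding_end <- 14L  # partial codon at the 3' end is trimmed
  ts2 <- TranscriptSet(c(t1 = "ATGAAACCCGGGTT"), species = "s",
                       annotation = ann)
  expect_equal(extractAnnotatedCds(ts2, "t1"), "ATGAAACCCGGG")

  # reverse strand: stored CAT slice becomes ATG after reverse complement
  ann3 <- data.frame(transcript_id = "t1", ref_gene_id = "g",
                     ref_protein_id = "p", coding_start = 2L,
                     coding_end = 11L, strand = -1L,
                     stringsAsFactors = FALSE)
  ts3 <- TranscriptSet(c(t1 = "AATTTGGGCATAA"), species = "s",
                       annotation = ann3)
  expect_equal(extractAnnotatedCds(ts3, "t1"), "ATGCCCAAA")

  # a trailing stop codon is trimmed
  ann4 <- data.frame(transcript_id = "t1", ref_gene_id = "g",
                     ref_protein_id = "p", coding_start = 0L,
                     coding_end = 9L, strand = 1L,
                     stringsAsFactors = FALSE)
  ts4 <- TranscriptSet(c(t1 = "ATGAAATAAC"), species = "s",
                       annotation = ann4)
  expect_equal(extractAnnotatedCds(ts4, "t1"), "ATGAAA")
})
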