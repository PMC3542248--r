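# Codon substitution simulator and fixture generator.

test_that("the rate matrix has the stated structure and scaling", {
  p <- codonSimParams(omega = 0.3, kappa = 2.5, t = 0.1, nCodons = 10)
  Q <- buildRateMatrix(p)
  expect_equal(max(abs(rowSums(Q))), 0, tolerance = 1e-12)
  # stationary total rate is 1 per codon per unit t
  expect_equal(-sum(p$pi * diag(Q)), 1, tolerance = 1e-12)
  # multi-nucleotide and stop-target rates are zero
  tab <- kaksScreen:::.codonTables()
  nt <- tab$nt
  for (i in c(1, 30, 60)) {
    for (j in seq_len(64)) {
      ndiff <- sum(nt[i, ] != nt[j, ])
      if (ndiff > 1 || !tab$sense[j] || !tab$sense[i])
        expect_equal(Q[i, j], 0)
    }
  }
})

test_that("omega = 0 forbids nonsynonymous change; kappa/omega = 1 is symmetric", {
  p0 <- codonSimParams(omega = 0, kappa = 2, t = 0.5, nCodons = 50,
                       seed = 61)
  Q0 <- buildRateMatrix(p0)
  tab <- kaksScreen:::.codonTables()
  aa <- tab$aa
  for (i in which(tab$sense))
    for (j in which(tab$sense))
      if (i != j && aa[i] != aa[j]) expect_equal(Q0[i, j], 0)
  sim <- simulateCodonPair(p0)
  aaOf <- function(cds) paste(
    Biostrings::GENETIC_CODE[splitCodonsForTest(cds)], collapse = "")
  expect_equal(aaOf(sim$cdsA), aaOf(sim$cdsB))

  p1 <- codonSimParams(omega = 1, kappa = 1, t = 0.1, nCodons = 10)
  Q1 <- buildRateMatrix(p1)
  offdiag <- Q1[Q1 > 0]
  expect_equal(length(unique(round(offdiag, 12))), 1L)
})

test_that("t = 0 yields identical sequences; a fixed seed reproduces exactly", {
  pz <- codonSimParams(t = 0, nCodons = 30, seed = 62)
  sz <- simulateCodonPair(pz)
  expect_equal(sz$cdsA, sz$cdsB)

  p <- codonSimParams(omega = 0.5, kappa = 2, t = 0.1, nCodons = 500,
                      seed = 77)
  s1 <- simulateCodonPair(p)
  s2 <- simulateCodonPair(p)
  expect_identical(s1$cdsA, s2$cdsA)
  expect_identical(s1$cdsB, s2$cdsB)
  expect_identical(s1$truth$syn_events, s2$truth$syn_events)
  expect_identical(s1$truth$nonsyn_events, s2$truth$nonsyn_events)
})

test_that("realized nonsynonymous proportion matches the matrix expectation", {
  # generator/estimator consistency over 200 replicate pairs
  set.seed(63)
  p <- codonSimParams(omega = 0.5, kappa = 2, t = 0.2, nCodons = 100)
  Q <- buildRateMatrix(p)
  tab <- kaksScreen:::.codonTables()
  fn <- 0
  for (i in which(tab$sense)) {
    sel <- !tab$syn[i, ] & !tab$stp[i, ]
    fn <- fn + p$pi[i] * sum(Q[i, tab$tgt[i, sel]])
  }
  syn <- non <- 0
  for (r in 1:200) {
    s <- simulateCodonPair(p)
    syn <- syn + s$truth$syn_events
    non <- non + s$truth$nonsyn_events
  }
  tot <- syn + non
  se <- sqrt(fn * (1 - fn) / tot)
  expect_lt(abs(non / tot - fn), 3 * se)
})

test_that("branch-length tuning hits the requested Ks on average", {
  set.seed(64)
  p <- tuneBranchLength(codonSimParams(omega = 0.2, kappa = 2,
                                       nCodons = 400), 0.05)
  ks <- replicate(40, simulateCodonPair(p)$truth$ks_true)
  expect_equal(mean(ks), 0.05, tolerance = 0.15)
})

test_that("fixtures are deterministic and the truth table covers every record once", {
  spec <- fixtureSpec(nOrthologPairs = 8, nStrong = 1,
                      nParalogDecoys = 1, nSpliceVariants = 1,
                      nNoncoding = 2, nUnannotated = 1, nCodons = 80,
                      seed = 65)
  f1 <- generateFixture(spec)
  f2 <- generateFixture(spec)
  expect_identical(as.character(transcriptSeqs(f1$tsA)),
                   as.character(transcriptSeqs(f2$tsA)))
  expect_identical(as.character(transcriptSeqs(f1$tsB)),
                   as.character(transcriptSeqs(f2$tsB)))
  expect_identical(f1$truth, f2$truth)

  allIds <- c(transcriptIds(f1$tsA), transcriptIds(f1$tsB))
  expect_setequal(f1$truth$transcript_id, allIds)
  expect_false(anyDuplicated(f1$truth$transcript_id) > 0)

  # role composition matches the spec
  roles <- table(f1$truth$role)
  expect_equal(unname(roles["strong_ortholog"]), 2L)
  expect_equal(unname(roles["paralog_decoy"]), 2L)
  expect_equal(unname(roles["splice_variant"]), 2L)
  expect_equal(unname(roles["noncoding"]), 2L)
  expect_equal(unname(roles["ortholog"]), 14L)

  # different seed: different sequences, same record counts
  f3 <- generateFixture(fixtureSpec(nOrthologPairs = 8, nStrong = 1,
                                    nParalogDecoys = 1,
                                    nSpliceVariants = 1, nNoncoding = 2,
                                    nUnannotated = 1, nCodons = 80,
                                    seed = 99))
  expect_false(identical(as.character(transcriptSeqs(f1$tsA)),
                         as.character(transcriptSeqs(f3$tsA))))
  expect_equal(nrow(f3$truth), nrow(f1$truth))
})

test_that("noncoding decoys carry no qualifying ORF and paralog decoys exceed Ks 0.1", {
  spec <- fixtureSpec(nOrthologPairs = 4, nStrong = 0,
                      nParalogDecoys = 2, nSpliceVariants = 0,
                      nNoncoding = 4, nUnannotated = 0, nCodons = 100,
                      seed = 66)
  fix <- generateFixture(spec)
  nc <- fix$truth$transcript_id[fix$truth$role == "noncoding"]
  for (id in nc) {
    ts <- if (grepl("spA", id)) fix$tsA else fix$tsB
    s <- as.character(transcriptSeqs(ts)[[id]])
    expect_null(longestOrf(setNames(s, id), minNt = 300))
  }
  para <- fix$truth[fix$truth$role == "paralog_decoy", ]
  expect_true(all(para$ks_true > 0.1))
})

test_that("unattainable fixture specs are rejected before generation", {
  expect_error(fixtureSpec(paralogTargetKs = 0.05),
               "exceed the 0.1 exclusion")
  expect_error(fixtureSpec(targetKsBackground = 0.3,
                           paralogTargetKs = 0.2),
               "must exceed the ortholog")
  expect_error(fixtureSpec(nStrong = 10, nOrthologPairs = 5))
})
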