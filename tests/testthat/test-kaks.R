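# Ka/Ks estimation: site counting, pathway-averaged differences,
# corrections, kappa estimation, classification, paralog filtering.

test_that("NG86 site counts match hand enumeration for canonical codons", {
  # TTT: of the 9 changes only TTT->TTC is synonymous
  expect_equal(ng86Sites("TTT"), c(S = 1 / 3, N = 8 / 3))
  # GGG: all third-position changes synonymous (glycine)
  expect_equal(ng86Sites("GGG"), c(S = 1, N = 2))
  # additivity over codons
  expect_equal(ng86Sites("TTTGGG"), c(S = 4 / 3, N = 14 / 3))
  expect_error(ng86Sites(""), "empty")
})

test_that("pathway-averaged differences match hand-worked cases", {
  expect_equal(ng86Diffs("TTT", "TTC"),
               c(Sd = 1, Nd = 0, excluded = 0))
  # TTT vs CTC: paths via CTT and TTC average to one of each type
  expect_equal(ng86Diffs("TTT", "CTC"),
               c(Sd = 1, Nd = 1, excluded = 0))
  expect_equal(ng86Diffs("AAAGGG", "AAAGGG"),
               c(Sd = 0, Nd = 0, excluded = 0))
})

test_that("difference counts are conserved: Sd + Nd equals the pathway-averaged total", {
  set.seed(51)
  for (i in 1:10) {
    a <- randomCds(50)
    b <- randomCds(50)
    d <- ng86Diffs(a, b)
    ca <- splitCodonsForTest(a); cb <- splitCodonsForTest(b)
    perCol <- mapply(function(x, y)
      sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]), ca, cb)
    excl <- logical(50)
    for (j in which(perCol > 0))
      excl[j] <- is.na(oracleDiffs(ca[j], cb[j])[1])
    expect_equal(unname(d["excluded"]), sum(excl))
    expect_equal(unname(d["Sd"] + d["Nd"]), sum(perCol[!excl]))
  }
})

test_that("NG86 Ka/Ks reproduces the independent oracle on random alignments", {
  set.seed(52)
  for (i in 1:8) {
    a <- randomCds(80)
    bCod <- splitCodonsForTest(a)
    swap <- sample(80, 12)
    bCod[swap] <- sample(oracleSenseCodons(), 12, replace = TRUE)
    b <- paste(bCod, collapse = "")
    res <- kaksNG86(gaplessAlignment(a, b))
    Sa <- sum(vapply(splitCodonsForTest(a), oracleSites, numeric(1)))
    Sb <- sum(vapply(splitCodonsForTest(b), oracleSites, numeric(1)))
    S <- (Sa + Sb) / 2
    d <- mapply(function(x, y) oracleDiffs(x, y),
                splitCodonsForTest(a), bCod)
    ok <- !is.na(d[1, ])
    Sd <- sum(d[1, ok]); Nd <- sum(d[2, ok])
    expect_equal(res@S, S)
    expect_equal(res@Sd, Sd)
    expect_equal(res@Nd, Nd)
    if (res@bucket == "both") {
      N <- 3 * 80 - S
      expect_equal(res@ratio, jcCorrection(Nd / N) / jcCorrection(Sd / S))
    }
  }
})

test_that("the worked Jukes-Cantor example evaluates as computed by hand", {
  # 300-codon pair, Sd = 5, Nd = 5, S = 234.5, N = 665.5
  ratio <- jcCorrection(5 / 665.5) / jcCorrection(5 / 234.5)
  expect_equal(ratio, 0.3490852, tolerance = 1e-6)
})

test_that("Jukes-Cantor correction approaches identity as p -> 0 and saturates at 3/4", {
  p <- 1e-4
  expect_equal(jcCorrection(p) / p, 1, tolerance = 1e-3)
  expect_true(is.na(jcCorrection(0.75)))
  expect_true(is.na(jcCorrection(0.9)))
})

test_that("buckets and ratio definedness follow the accounting rules", {
  a <- randomCds(100)
  resId <- kaksNG86(gaplessAlignment(a, a))
  expect_equal(resId@bucket, "identical")
  expect_true(is.na(resId@ratio))
  expect_equal(resId@Ka, 0)
  expect_equal(resId@Ks, 0)

  base <- paste(rep("GGGAAATTT", 40), collapse = "")
  syn <- setCodon(base, 1, "GGA")   # Gly synonymous change
  resSyn <- kaksNG86(gaplessAlignment(base, syn))
  expect_equal(resSyn@bucket, "syn_only")
  expect_true(is.na(resSyn@ratio))

  non <- setCodon(setCodon(base, 2, "CAA"), 5, "CAA")  # Lys->Gln twice
  resNon <- kaksNG86(gaplessAlignment(base, non))
  expect_equal(resNon@bucket, "nonsyn_only")
  expect_equal(resNon@Nd, 2)
  expect_true(is.na(resNon@ratio))

  both <- setCodon(syn, 2, "CAA")
  resBoth <- kaksNG86(gaplessAlignment(base, both))
  expect_equal(resBoth@bucket, "both")
  expect_false(is.na(resBoth@ratio))
})

test_that("estimators are invariant under swapping the two sequences", {
  set.seed(53)
  p <- codonSimParams(omega = 0.5, kappa = 2, t = 0.15, nCodons = 200)
  sim <- simulateCodonPair(p)
  for (fun in list(kaksNG86, kaksYN)) {
    r1 <- fun(gaplessAlignment(sim$cdsA, sim$cdsB))
    r2 <- fun(gaplessAlignment(sim$cdsB, sim$cdsA))
    for (sl in c("S", "N", "Sd", "Nd", "Ka", "Ks", "kappa"))
      expect_equal(methods::slot(r1, sl), methods::slot(r2, sl))
  }
})

test_that("kappa estimation handles the no-information and balanced cases", {
  a <- randomCds(100)
  k0 <- estimateKappa(gaplessAlignment(a, a))
  expect_equal(as.numeric(k0), 1)
  expect_match(attr(k0, "note"), "fallback", all = FALSE)

  # 100 fourfold third positions: 5 transitions, 10 transversions.
  # Per-type rates are then equal (two transversion targets per site),
  # so kappa is exactly 1.
  aCod <- rep("GGG", 100)
  bCod <- aCod
  bCod[1:5] <- "GGA"    # G->A transition
  bCod[6:15] <- "GGC"   # G->C transversion
  kb <- estimateKappa(gaplessAlignment(paste(aCod, collapse = ""),
                                       paste(bCod, collapse = "")))
  expect_equal(as.numeric(kb), 1, tolerance = 1e-12)
})

test_that("kappa is recovered from data simulated at kappa = 2", {
  set.seed(54)
  p <- codonSimParams(omega = 1, kappa = 2, t = 0.3, nCodons = 2000)
  sim <- simulateCodonPair(p)
  k <- estimateKappa(gaplessAlignment(sim$cdsA, sim$cdsB))
  expect_gt(as.numeric(k), 1.4)
  expect_lt(as.numeric(k), 2.8)
})

test_that("the YN estimator collapses to NG86 at kappa 1 / uniform frequencies", {
  set.seed(55)
  p <- codonSimParams(omega = 0.4, kappa = 3, t = 0.2, nCodons = 300)
  sim <- simulateCodonPair(p)
  aln <- gaplessAlignment(sim$cdsA, sim$cdsB)
  rNG <- kaksNG86(aln)
  rYN <- kaksYN(aln, kappa = 1, codonFreqs = "uniform")
  expect_equal(rYN@Ka, rNG@Ka, tolerance = 1e-12)
  expect_equal(rYN@Ks, rNG@Ks, tolerance = 1e-12)
})

test_that("paralog filtering removes Ks strictly above 0.1 only", {
  res <- data.frame(pair_id = c("p1", "p2", "p3", "p4"),
                    Ks = c(0.15, 0.05, 0.10, NA),
                    stringsAsFactors = FALSE)
  out <- filterParalogs(res, ksMax = 0.1)
  expect_setequal(out$pair_id, c("p2", "p3", "p4"))
  expect_equal(attr(out, "removed")$pair_id, "p1")
})

test_that("candidate classification applies the 0.5 and 1.0 cut-offs", {
  expect_equal(classifyCandidate(c(1.7284, 1.0342, 1.0, 0.5062, 0.5,
                                   0.1452, NA)),
               c("strong", "strong", "candidate", "candidate",
                 "non_candidate", "non_candidate", "unclassifiable"))
})

test_that("F3x4 frequencies are a valid distribution over sense codons", {
  set.seed(56)
  a <- randomCds(100); b <- randomCds(100)
  pi64 <- f3x4Frequencies(gaplessAlignment(a, b))
  expect_equal(sum(pi64), 1)
  expect_true(all(pi64 >= 0))
  stops <- c("TAA", "TAG", "TGA")
  tabIdx <- match(stops, names(Biostrings::GENETIC_CODE))
  # stop codons carry zero frequency
  expect_equal(unname(pi64[kaksScreen:::.codonTables()$codonIndex[stops]]),
               c(0, 0, 0))
})
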