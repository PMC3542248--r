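# Translated search, reciprocal best hits and redundancy collapse.

mkTs <- function(seqs, species) TranscriptSet(seqs, species = species)

test_that("an identical 200-codon pair is a high-identity hit above 300 bits", {
  set.seed(5)
  cds <- randomCds(200)
  q <- mkTs(c(q1 = cds), "qs")
  s <- mkTs(c(s1 = cds), "ss")
  hits <- translatedSearch(q, s)
  expect_equal(nrow(hits), 1L)
  expect_gte(hits$bit_score, 300)
  expect_equal(hits$identity_fraction, 1.0)
  expect_equal(hits$aligned_length, 200)
  expect_equal(hits$query_frame, 1)
})

test_that("short random sequences cannot reach 300 bits", {
  set.seed(6)
  q <- mkTs(c(q1 = paste(sample(c("A","C","G","T"), 40, TRUE),
                         collapse = "")), "qs")
  s <- mkTs(c(s1 = paste(sample(c("A","C","G","T"), 40, TRUE),
                         collapse = "")), "ss")
  expect_equal(nrow(translatedSearch(q, s)), 0L)
})

test_that("the bit threshold is applied before best-hit selection", {
  set.seed(8)
  cds <- randomCds(120)
  q <- mkTs(c(q1 = cds), "qs")
  s <- mkTs(c(s1 = cds), "ss")
  full <- translatedSearch(q, s, bitThreshold = 1)
  b <- full$bit_score[1]
  expect_equal(nrow(translatedSearch(q, s, bitThreshold = b)), 1L)
  expect_equal(nrow(translatedSearch(q, s, bitThreshold = b + 0.1)), 0L)
})

test_that("a transcript never hits itself in intra-set use", {
  set.seed(9)
  cds <- randomCds(150)
  ts <- mkTs(c(t1 = cds, t2 = cds), "sp")
  hits <- translatedSearch(ts, ts, bitThreshold = 100)
  expect_false(any(hits$query_id == hits$subject_id))
  expect_setequal(paste(hits$query_id, hits$subject_id),
                  c("t1 t2", "t2 t1"))
})

test_that("reciprocal best hits agree with all-vs-all brute force on a 2x2 toy", {
  hit <- function(q, s, bit, ident = 0.9)
    data.frame(query_id = q, subject_id = s, query_frame = 1,
               subject_frame = 1, raw_score = bit, bit_score = bit,
               aligned_length = 100, identity_fraction = ident,
               stringsAsFactors = FALSE)
  # a1<->b1 mutual best among {a1,a2} x {b1,b2}
  ab <- rbind(hit("a1", "b1", 500), hit("a1", "b2", 400),
              hit("a2", "b1", 450), hit("a2", "b2", 350))
  ba <- rbind(hit("b1", "a1", 500), hit("b1", "a2", 450),
              hit("b2", "a1", 400), hit("b2", "a2", 350))
  rbh <- reciprocalBestHits(ab, ba)
  expect_equal(rbh$id_a, "a1")
  expect_equal(rbh$id_b, "b1")

  # asymmetry: a1's best is b1 but b1's best is a2 -> no (a1, b1) pair
  ba2 <- rbind(hit("b1", "a2", 600), hit("b1", "a1", 500))
  rbh2 <- reciprocalBestHits(ab[1:2, ], ba2)
  expect_false(any(rbh2$id_a == "a1" & rbh2$id_b == "b1"))

  # exact bit tie broken by higher identity
  ab3 <- rbind(hit("a1", "b1", 500, ident = 0.99),
               hit("a1", "b2", 500, ident = 0.90))
  ba3 <- rbind(hit("b1", "a1", 500), hit("b2", "a1", 500))
  rbh3 <- reciprocalBestHits(ab3, ba3)
  expect_equal(rbh3$id_b, "b1")

  # full tie broken by lexicographically smaller subject id
  ab4 <- rbind(hit("a1", "b2", 500), hit("a1", "b1", 500))
  ba4 <- rbind(hit("b1", "a1", 500), hit("b2", "a1", 500))
  expect_equal(reciprocalBestHits(ab4, ba4)$id_b, "b1")
})

test_that("RBH output is symmetric in the two species' roles", {
  set.seed(10)
  spec <- fixtureSpec(nOrthologPairs = 6, nStrong = 0,
                      nParalogDecoys = 0, nSpliceVariants = 0,
                      nNoncoding = 2, nUnannotated = 0, nCodons = 170,
                      seed = 17)
  fix <- generateFixture(spec)
  hAB <- translatedSearch(fix$tsA, fix$tsB)
  hBA <- translatedSearch(fix$tsB, fix$tsA)
  r1 <- reciprocalBestHits(hAB, hBA)
  r2 <- reciprocalBestHits(hBA, hAB)
  expect_setequal(paste(r1$id_a, r1$id_b), paste(r2$id_b, r2$id_a))
  # planted one-to-one orthologs, no confounders: recall is 100%
  expect_equal(nrow(r1), 6L)
  expect_true(all(sub("spA_", "", r1$id_a) == sub("spB_", "", r1$id_b)))
  # no transcript appears twice
  expect_false(anyDuplicated(c(r1$id_a, r1$id_b)) > 0)
})

test_that("redundancy collapse keeps the longest pair per overlapping gene region", {
  pair <- function(ida, idb, gene, len, rs, re)
    data.frame(id_a = ida, id_b = idb, ref_gene_id = gene,
               cds_a = strrep("A", len), cds_b = strrep("A", len),
               source = "annotated", ref_start = rs, ref_end = re,
               stringsAsFactors = FALSE)
  # overlapping regions on one gene: total lengths 900 vs 600
  p <- rbind(pair("a1", "b1", "g1", 450, 0, 150),
             pair("a2", "b2", "g1", 300, 50, 150))
  out <- collapseRedundant(p)
  expect_equal(out$id_a, "a1")
  expect_equal(attr(out, "removed")$id_a, "a2")

  # disjoint regions on the same gene: both kept
  p2 <- rbind(pair("a1", "b1", "g1", 450, 0, 100),
              pair("a2", "b2", "g1", 300, 120, 200))
  expect_equal(nrow(collapseRedundant(p2)), 2L)

  # different genes: untouched
  p3 <- rbind(pair("a1", "b1", "g1", 450, 0, 100),
              pair("a2", "b2", "g2", 300, 0, 100))
  expect_equal(nrow(collapseRedundant(p3)), 2L)
})
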