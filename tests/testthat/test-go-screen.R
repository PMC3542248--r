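# GO aggregation: levels, per-term means, category rollup, a-priori
# screen.

test_that("GO levels are minimum is_a depths with root at level 1", {
  onto <- tinyOntology()
  expect_equal(goLevel("root", onto), 1L)
  expect_equal(goLevel(c("a", "c"), onto), c(2L, 2L))
  expect_equal(goLevel("b", onto), 3L)
  # d has parents at levels 3 (b) and 2 (c): min path gives level 3
  expect_equal(goLevel("d", onto), 3L)
  expect_true(is.na(goLevel("orphan", onto)))
})

mkResults <- function(genes, ratios, classes = NULL) {
  if (is.null(classes)) classes <- classifyCandidate(ratios)
  data.frame(pair_id = paste0("p_", genes), ref_gene_id = genes,
             ratio = ratios, class = classes, stringsAsFactors = FALSE)
}

test_that("per-term means obey the minimum-ortholog rule", {
  genes <- paste0("g", 1:11)
  ratios <- c(seq(0.1, 0.9, length.out = 9), 0.2, 0.4)
  go <- rbind(
    data.frame(gene_id = genes[1:9], term_id = "t9"),    # 9 orthologs
    data.frame(gene_id = genes, term_id = "t11"),        # 11 orthologs
    data.frame(gene_id = genes[10:11], term_id = "t2"))  # 2 orthologs
  res <- mkResults(genes, ratios)
  out10 <- termMeanRatio(res, go, minN = 10)
  expect_equal(out10$term_id, "t11")     # t9 suppressed below minN
  expect_equal(out10$mean_ratio, mean(ratios))
  out2 <- termMeanRatio(res, go, minN = 2)
  expect_equal(out2$mean_ratio[out2$term_id == "t2"], 0.3)
  # ranked descending by mean
  expect_true(!is.unsorted(rev(out2$mean_ratio)))
})

test_that("terms whose orthologs all lack ratios are suppressed with a warning", {
  genes <- paste0("g", 1:3)
  res <- mkResults(genes, c(NA, NA, NA),
                   classes = rep("unclassifiable", 3))
  go <- data.frame(gene_id = genes, term_id = "t1")
  expect_warning(out <- termMeanRatio(res, go, minN = 3),
                 "no defined ratios")
  expect_equal(nrow(out), 0L)
})

test_that("per-term means are invariant under input permutation", {
  set.seed(71)
  genes <- paste0("g", 1:20)
  ratios <- runif(20)
  go <- data.frame(gene_id = rep(genes, 2),
                   term_id = sample(c("t1", "t2", "t3"), 40,
                                    replace = TRUE))
  res <- mkResults(genes, ratios)
  o1 <- termMeanRatio(res, go, minN = 1)
  perm <- sample(nrow(go))
  o2 <- termMeanRatio(res[sample(20), ], go[perm, ], minN = 1)
  expect_equal(o1, o2)
})

test_that("category distribution rolls annotations up to the requested level", {
  onto <- tinyOntology()
  # 50 candidates, 2 of them under level-3 term b (one via leaf d)
  candGenes <- paste0("c", 1:50)
  nonGenes <- paste0("n", 1:40)
  res <- rbind(mkResults(candGenes, rep(0.8, 50)),
               mkResults(nonGenes, rep(0.1, 40)))
  go <- rbind(
    data.frame(gene_id = c("c1", "c2"), term_id = c("b", "d")),
    data.frame(gene_id = nonGenes[1:10], term_id = "d"),
    data.frame(gene_id = c(candGenes, nonGenes), term_id = "a"))
  out <- categoryDistribution(res, go, onto, level = 3)
  b <- out[out$term_id == "b", ]
  expect_equal(b$n_candidate, 2L)
  expect_equal(b$pct_candidate, 4.0)     # 2 of 50
  expect_equal(b$n_noncandidate, 10L)    # via descendant d
  expect_equal(b$pct_noncandidate, 25.0)
  expect_false(b$candidate_enriched)
  # every classified gene is in exactly one of the two sets
  expect_equal(length(unique(res$ref_gene_id)), 90L)
})

test_that("identical annotation patterns flag no term as enriched", {
  onto <- tinyOntology()
  res <- rbind(mkResults(paste0("c", 1:10), rep(0.8, 10)),
               mkResults(paste0("n", 1:10), rep(0.1, 10)))
  go <- data.frame(gene_id = c(paste0("c", 1:5), paste0("n", 1:5)),
                   term_id = "b")
  out <- categoryDistribution(res, go, onto, level = 3)
  expect_false(any(out$candidate_enriched))
})

test_that("the two-step screen matches listed terms directly and via descendants", {
  res <- mkResults(c("g1", "g2", "g3", "g4"),
                   c(1.5, 0.8, 0.9, 0.2))
  onto <- toyOntology()
  go <- rbind(
    data.frame(gene_id = "g1", term_id = "GO:0019825"),  # step 1
    data.frame(gene_id = "g2", term_id = "GO:0009411"),  # step 2
    data.frame(gene_id = "g3", term_id = "GO:0006412"),  # unlisted
    data.frame(gene_id = "g4", term_id = "GO:0001666"))  # non-candidate
  hits <- functionalScreen(res, go, edges = onto$edges)
  expect_setequal(hits$ref_gene_id, c("g1", "g2"))
  expect_equal(hits$step[hits$ref_gene_id == "g1"], "hypoxia_list")
  expect_equal(hits$step[hits$ref_gene_id == "g2"],
               "poikilotherm_list")
  expect_true(all(hits$ratio > 0.5))

  # unknown list id: warned about and skipped
  expect_warning(
    functionalScreen(res, go, step1Terms = c("GO:0019825", "GO:9999999"),
                     edges = onto$edges),
    "not in the ontology")
})

test_that("default screen term lists ship with the package", {
  s1 <- defaultScreenTerms("hypoxia")
  s2 <- defaultScreenTerms("poikilotherm")
  expect_true(all(c("GO:0001666", "GO:0019825") %in% s1))
  expect_true(all(c("GO:0009411", "GO:0006749", "GO:0006200") %in% s2))
})
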