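# Shared helpers for building tiny in-code fixtures.

# random stop-free coding sequence of n codons
randomCds <- function(n) {
  sense <- oracleSenseCodons()
  paste(sample(sense, n, replace = TRUE), collapse = "")
}

# a CodonAlignment built directly from two equal-length gapless CDSs
# (bypasses the aligner; for estimator tests where the alignment is known)
gaplessAlignment <- function(cdsA, cdsB, id = "pair") {
  methods::new("CodonAlignment", pairId = id, alnA = cdsA, alnB = cdsB,
               comparedCodons = as.integer(nchar(cdsA) / 3),
               ambiguousCodons = 0L, status = "pass", reason = "")
}

# simulate a pair and wrap it as an alignment (pairs are gapless by
# construction)
simulatedAlignment <- function(params, id = "sim") {
  sim <- simulateCodonPair(params)
  list(alignment = gaplessAlignment(sim$cdsA, sim$cdsB, id),
       truth = sim$truth)
}

splitCodonsForTest <- function(x)
  substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))

# substitute codon number i (1-based) of a codon string
setCodon <- function(cds, i, codon) {
  paste0(substr(cds, 1, (i - 1) * 3), codon,
         substr(cds, i * 3 + 1, nchar(cds)))
}

# tiny ontology used by GO unit tests: one namespace, five terms
#   root(1) -> a(2) -> b(3) -> d(4)
#   root(1) -> c(2);  d also is_a c  (so d's min level is 3)
tinyOntology <- function() {
  data.frame(
    child = c("a", "b", "d", "c", "d"),
    parent = c("root", "a", "b", "root", "c"),
    relation = "is_a", namespace = "ns",
    stringsAsFactors = FALSE)
}
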