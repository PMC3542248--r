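# Independent brute-force oracle for NG86 site and difference counting,
# written directly against the genetic code with plain string operations.
# Deliberately shares no code with the package internals.

.oracleBases <- c("A", "C", "G", "T")
.oracleCode <- Biostrings::GENETIC_CODE

oracleTranslate <- function(codon) unname(.oracleCode[[codon]])

oracleIsStop <- function(codon) oracleTranslate(codon) == "*"

# synonymous site count of one codon: per position, fraction of
# synonymous changes among non-stop single-nucleotide changes
oracleSites <- function(codon) {
  stopifnot(!oracleIsStop(codon))
  s <- 0
  for (p in 1:3) {
    nSyn <- 0; nOk <- 0
    for (b in setdiff(.oracleBases, substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- b
      if (oracleIsStop(mut)) next
      nOk <- nOk + 1
      if (oracleTranslate(mut) == oracleTranslate(codon))
        nSyn <- nSyn + 1
    }
    if (nOk > 0) s <- s + nSyn / nOk
  }
  s
}

# all permutations of 1..k, written out
.oraclePerms <- function(k) {
  if (k == 1) return(list(1L))
  if (k == 2) return(list(c(1L, 2L), c(2L, 1L)))
  out <- list()
  for (a in 1:3) for (b in setdiff(1:3, a))
    out[[length(out) + 1L]] <- c(a, b, setdiff(1:3, c(a, b)))
  out
}

# pathway-averaged (Sd, Nd) between two sense codons; NA when every
# ordering passes through a stop codon
oracleDiffs <- function(c1, c2) {
  dpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(dpos)
  if (k == 0) return(c(Sd = 0, Nd = 0))
  tot <- c(0, 0); nValid <- 0
  for (ord in .oraclePerms(k)) {
    cur <- c1
    step <- c(0, 0)
    blocked <- FALSE
    for (p in dpos[ord]) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (oracleIsStop(nxt)) { blocked <- TRUE; break }
      if (oracleTranslate(nxt) == oracleTranslate(cur))
        step[1] <- step[1] + 1
      else step[2] <- step[2] + 1
      cur <- nxt
    }
    if (!blocked) { tot <- tot + step; nValid <- nValid + 1 }
  }
  if (nValid == 0) return(c(Sd = NA_real_, Nd = NA_real_))
  c(Sd = tot[1] / nValid, Nd = tot[2] / nValid)
}

oracleSenseCodons <- function() {
  cods <- apply(expand.grid(.oracleBases, .oracleBases, .oracleBases),
                1, paste, collapse = "")
  cods[vapply(cods, function(x) !oracleIsStop(x), logical(1))]
}
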