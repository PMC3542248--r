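# Internal codon bookkeeping shared by the Ka/Ks estimators and the
# simulator. Everything is derived once from the standard genetic code
# (Biostrings::GENETIC_CODE) and cached.

.kaks_cache <- new.env(parent = emptyenv())

.BASES <- c("T", "C", "A", "G")

# transition partners: A<->G, C<->T
.isTransition <- function(from, to) {
  (from == "A" & to == "G") | (from == "G" & to == "A") |
    (from == "C" & to == "T") | (from == "T" & to == "C")
}

#' @noRd
.codonTables <- function(geneticCode = Biostrings::GENETIC_CODE) {
  key <- paste0("tab_", paste(geneticCode, collapse = ""))
  if (!is.null(.kaks_cache[[key]])) return(.kaks_cache[[key]])

  grid <- expand.grid(p3 = .BASES, p2 = .BASES, p1 = .BASES,
                      stringsAsFactors = FALSE)
  codons <- paste0(grid$p1, grid$p2, grid$p3)
  aa <- unname(geneticCode[codons])
  stopifnot(!anyNA(aa))
  sense <- aa != "*"
  nt <- cbind(substr(codons, 1, 1), substr(codons, 2, 2), substr(codons, 3, 3))

  # neighbor structure: 9 single-nucleotide changes per codon
  n <- length(codons)
  tgt  <- matrix(0L, n, 9)       # target codon index
  pos  <- matrix(0L, n, 9)       # which codon position changed (1..3)
  ts   <- matrix(FALSE, n, 9)    # transition?
  syn  <- matrix(FALSE, n, 9)    # synonymous?
  stp  <- matrix(FALSE, n, 9)    # target is a stop codon?
  codonIndex <- setNames(seq_len(n), codons)
  for (i in seq_len(n)) {
    k <- 0L
    for (p in 1:3) {
      for (b in setdiff(.BASES, nt[i, p])) {
        k <- k + 1L
        ntj <- nt[i, ]
        ntj[p] <- b
        j <- codonIndex[[paste0(ntj[1], ntj[2], ntj[3])]]
        tgt[i, k] <- j
        pos[i, k] <- p
        ts[i, k] <- .isTransition(nt[i, p], b)
        syn[i, k] <- identical(aa[i], aa[j])
        stp[i, k] <- !sense[j]
      }
    }
  }

  # degeneracy: number of synonymous changes among the 3 at each position
  deg <- matrix(0L, n, 3)
  for (p in 1:3) deg[, p] <- rowSums(syn[, pos[1, ] == p] & !stp[, pos[1, ] == p])
  # pos rows are identical across codons (same enumeration order); verify
  stopifnot(all(apply(pos, 2, function(x) length(unique(x)) == 1L)))

  tab <- list(codons = codons, aa = aa, sense = sense, nt = nt,
              codonIndex = codonIndex, tgt = tgt, pos = pos, ts = ts,
              syn = syn, stp = stp, deg = deg,
              posCol = pos[1, ])  # position of each of the 9 change slots
  .kaks_cache[[key]] <- tab
  tab
}

# NG86 per-codon synonymous site counts (vector over the 64 codons; NA for
# stops). stopHandling "exclude" renormalizes each position over its
# non-stop changes; "nonsynonymous" keeps the classical divisor of 3.
#' @noRd
.ng86SiteVector <- function(stopHandling = c("exclude", "nonsynonymous"),
                            tab = .codonTables()) {
  stopHandling <- match.arg(stopHandling)
  key <- paste0("sites_", stopHandling)
  if (!is.null(.kaks_cache[[key]])) return(.kaks_cache[[key]])
  S <- rep(NA_real_, length(tab$codons))
  for (i in which(tab$sense)) {
    s <- 0
    for (p in 1:3) {
      sel <- tab$posCol == p
      nSyn <- sum(tab$syn[i, sel] & !tab$stp[i, sel])
      if (stopHandling == "exclude") {
        nOk <- sum(!tab$stp[i, sel])
        s <- s + if (nOk > 0) nSyn / nOk else 0
      } else {
        s <- s + nSyn / 3
      }
    }
    S[i] <- s
  }
  .kaks_cache[[key]] <- S
  S
}

# Kappa/frequency-weighted synonymous site counts for every sense codon:
# each candidate change is weighted by kappa (transitions) times the
# stationary frequency of the target codon; the synonymous fraction at a
# position is the weighted share of synonymous changes among non-stop ones.
# codonFreqs: length-64 vector (stop entries ignored), need not be
# normalized. Returns vector over 64 codons (NA for stops).
#' @noRd
.weightedSiteVector <- function(kappa, codonFreqs, tab = .codonTables()) {
  S <- rep(NA_real_, length(tab$codons))
  w64 <- ifelse(tab$sense, codonFreqs, 0)
  for (i in which(tab$sense)) {
    s <- 0
    for (p in 1:3) {
      sel <- tab$posCol == p & !tab$stp[i, ]
      if (!any(sel)) next
      w <- w64[tab$tgt[i, sel]] * ifelse(tab$ts[i, sel], kappa, 1)
      tot <- sum(w)
      if (tot <= 0) {           # degenerate frequencies: fall back to counts
        w <- ifelse(tab$ts[i, sel], kappa, 1)
        tot <- sum(w)
      }
      s <- s + sum(w[tab$syn[i, sel]]) / tot
    }
    S[i] <- s
  }
  S
}

# Pathway-averaged difference counts for every ordered sense-codon pair.
# Multi-difference codons are averaged over all orderings of the single
# nucleotide steps, excluding paths through stop codons with equal weight on
# the remainder. Matrices are 64x64; ok[i,j] FALSE marks pairs where every
# path crosses a stop (column must be excluded and tallied).
#' @noRd
.pathTables <- function(tab = .codonTables()) {
  if (!is.null(.kaks_cache$paths)) return(.kaks_cache$paths)
  n <- length(tab$codons)
  sdts <- sdtv <- ndts <- ndtv <- matrix(0, n, n)
  ok <- matrix(FALSE, n, n)
  perms <- list(`1` = matrix(1L, 1, 1),
                `2` = rbind(c(1L, 2L), c(2L, 1L)),
                `3` = {
                  m <- NULL
                  for (a in 1:3) for (b in setdiff(1:3, a))
                    m <- rbind(m, c(a, b, setdiff(1:3, c(a, b))))
                  m
                })
  senseIdx <- which(tab$sense)
  for (i in senseIdx) {
    for (j in senseIdx) {
      dpos <- which(tab$nt[i, ] != tab$nt[j, ])
      k <- length(dpos)
      if (k == 0L) { ok[i, j] <- TRUE; next }
      ords <- perms[[as.character(k)]]
      acc <- c(sts = 0, stv = 0, nts = 0, ntv = 0)
      nValid <- 0L
      for (r in seq_len(nrow(ords))) {
        cur <- tab$nt[i, ]
        step <- c(sts = 0, stv = 0, nts = 0, ntv = 0)
        valid <- TRUE
        for (p in dpos[ords[r, seq_len(k)]]) {
          fromCodon <- paste0(cur[1], cur[2], cur[3])
          fromIdx <- tab$codonIndex[[fromCodon]]
          cur[p] <- tab$nt[j, p]
          toIdx <- tab$codonIndex[[paste0(cur[1], cur[2], cur[3])]]
          if (!tab$sense[toIdx]) { valid <- FALSE; break }
          isTs <- .isTransition(tab$nt[i, p], tab$nt[j, p])
          isSyn <- identical(tab$aa[fromIdx], tab$aa[toIdx])
          slot <- paste0(if (isSyn) "s" else "n", if (isTs) "ts" else "tv")
          step[slot] <- step[slot] + 1
        }
        if (valid) {
          acc <- acc + step
          nValid <- nValid + 1L
        }
      }
      if (nValid > 0L) {
        acc <- acc / nValid
        sdts[i, j] <- acc[["sts"]]; sdtv[i, j] <- acc[["stv"]]
        ndts[i, j] <- acc[["nts"]]; ndtv[i, j] <- acc[["ntv"]]
        ok[i, j] <- TRUE
      }
    }
  }
  res <- list(sdts = sdts, sdtv = sdtv, ndts = ndts, ndtv = ndtv, ok = ok)
  .kaks_cache$paths <- res
  res
}

# split a gap-free codon string into codon indices (error on partial codons,
# non-ACGT characters, or stop codons if disallowed)
#' @noRd
.codonIndices <- function(cds, allowStops = FALSE, tab = .codonTables()) {
  if (!nzchar(cds)) stop("empty coding sequence")
  if (nchar(cds) %% 3 != 0)
    stop("coding sequence length is not a multiple of 3")
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  idx <- unname(tab$codonIndex[codons])
  if (anyNA(idx))
    stop("non-ACGT codon encountered: ", codons[which(is.na(idx))[1]])
  if (!allowStops && any(!tab$sense[idx]))
    stop("stop codon encountered at codon ",
         which(!tab$sense[idx])[1])
  idx
}
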