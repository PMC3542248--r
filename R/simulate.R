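# Goldman-Yang style codon substitution simulator and transcriptome
# fixture generator. The simulator provides ortholog pairs diverged under
# known omega (the quantity Ka/Ks estimates), kappa and branch length;
# the fixture generator embeds such pairs in transcripts with UTRs and
# adds the confounders the screen must handle: paralog-like deep pairs
# with elevated Ks, splice-variant redundancy, and noncoding decoys.
#
# Branch-length convention: t is the expected number of nucleotide
# substitutions per codon along the FULL path between the two sequences
# (each lineage evolves for t/2 from a common ancestor drawn from the
# stationary distribution). Evolution is simulated per site with an exact
# jump chain (exponential waiting times), so realized substitution counts
# in the truth record are exact event counts, not approximations.

#' Parameters for the codon-pair simulator
#'
#' @param omega Nonsynonymous/synonymous rate ratio (>= 0).
#' @param kappa Transition/transversion rate ratio (>= 0).
#' @param t Expected substitutions per codon along the full path between
#'   the two sequences.
#' @param nCodons Number of codons.
#' @param codonFreqs \code{"uniform"} or a length-64 frequency vector
#'   (stop entries ignored and zeroed).
#' @param seed Integer seed, or \code{NULL} to use the current RNG state.
#' @return A validated parameter list of class \code{CodonSimParams}.
#' @export
codonSimParams <- function(omega = 0.2, kappa = 2, t = 0.1,
                           nCodons = 500, codonFreqs = "uniform",
                           seed = NULL) {
  stopifnot(omega >= 0, kappa >= 0, t >= 0, nCodons >= 1)
  tab <- .codonTables()
  if (identical(codonFreqs, "uniform")) {
    pi64 <- .uniformCodonFreqs()
  } else {
    if (length(codonFreqs) != 64) stop("codonFreqs must have length 64")
    pi64 <- ifelse(tab$sense, codonFreqs, 0)
    if (sum(pi64) <= 0) stop("degenerate frequency vector")
    pi64 <- pi64 / sum(pi64)
  }
  structure(list(omega = omega, kappa = kappa, t = t, nCodons = nCodons,
                 pi = pi64, seed = seed), class = "CodonSimParams")
}

#' Build the codon substitution rate matrix
#'
#' Rate i -> j is zero for multi-nucleotide or stop-target changes and
#' otherwise proportional to the target frequency, times kappa for
#' transitions and omega for nonsynonymous changes. Rows sum to zero and
#' the matrix is scaled so the stationary expected substitution rate is
#' one per codon per unit \code{t}.
#'
#' @param params A \code{CodonSimParams}.
#' @return 64 x 64 rate matrix (stop rows/columns zero except the
#'   diagonal convention of zero) with codon dimnames.
#' @export
buildRateMatrix <- function(params) {
  stopifnot(inherits(params, "CodonSimParams"))
  tab <- .codonTables()
  n <- length(tab$codons)
  Q <- matrix(0, n, n, dimnames = list(tab$codons, tab$codons))
  for (i in which(tab$sense)) {
    ok <- !tab$stp[i, ]
    j <- tab$tgt[i, ok]
    rate <- params$pi[j] *
      ifelse(tab$ts[i, ok], params$kappa, 1) *
      ifelse(tab$syn[i, ok], 1, params$omega)
    Q[i, j] <- rate
  }
  diag(Q) <- -rowSums(Q)
  scale <- -sum(params$pi * diag(Q))
  if (scale <= 0) {
    if (params$omega == 0 && params$t == 0) return(Q)
    if (scale == 0) stop("rate matrix has zero total rate")
  }
  Q / scale
}

# evolve integer codon states for a duration by per-site jump chains
#' @noRd
.evolveCodons <- function(idx, time, Q, events = FALSE) {
  tab <- .codonTables()
  leave <- -diag(Q)
  ev <- list(syn_ts = 0L, syn_tv = 0L, nonsyn_ts = 0L, nonsyn_tv = 0L)
  if (time <= 0) return(list(idx = idx, events = ev))
  remaining <- rep(time, length(idx))
  active <- which(leave[idx] > 0)
  while (length(active)) {
    wait <- rexp(length(active), rate = leave[idx[active]])
    jump <- wait < remaining[active]
    remaining[active] <- remaining[active] - wait
    jumpers <- active[jump]
    for (s in jumpers) {
      i <- idx[s]
      rates <- Q[i, ]
      rates[i] <- 0
      j <- sample.int(length(rates), 1L, prob = rates)
      if (events) {
        isSyn <- identical(tab$aa[i], tab$aa[j])
        pos <- which(tab$nt[i, ] != tab$nt[j, ])[1]
        isTs <- .isTransition(tab$nt[i, pos], tab$nt[j, pos])
        slot <- paste0(if (isSyn) "syn" else "nonsyn",
                       if (isTs) "_ts" else "_tv")
        ev[[slot]] <- ev[[slot]] + 1L
      }
      idx[s] <- j
    }
    active <- jumpers[leave[idx[jumpers]] > 0]
  }
  list(idx = idx, events = ev)
}

#' Simulate one diverged coding-sequence pair
#'
#' Draws an ancestor from the stationary distribution and evolves each
#' lineage for \code{t/2}. The truth record stores the realized
#' synonymous/nonsynonymous (and transition/transversion) substitution
#' counts summed over both lineages, plus truth-level Ka/Ks computed from
#' realized events over NG86 site counts of the ancestor.
#'
#' @param params A \code{CodonSimParams}.
#' @return List with \code{cdsA}, \code{cdsB} (codon strings) and
#'   \code{truth} (named list).
#' @export
simulateCodonPair <- function(params) {
  stopifnot(inherits(params, "CodonSimParams"))
  if (!is.null(params$seed)) set.seed(params$seed)
  tab <- .codonTables()
  Q <- buildRateMatrix(params)
  anc <- sample.int(64L, params$nCodons, replace = TRUE, prob = params$pi)
  la <- .evolveCodons(anc, params$t / 2, Q, events = TRUE)
  lb <- .evolveCodons(anc, params$t / 2, Q, events = TRUE)
  synEv <- la$events$syn_ts + la$events$syn_tv +
    lb$events$syn_ts + lb$events$syn_tv
  nonEv <- la$events$nonsyn_ts + la$events$nonsyn_tv +
    lb$events$nonsyn_ts + lb$events$nonsyn_tv
  sv <- .ng86SiteVector("exclude")
  Sanc <- sum(sv[anc])
  Nanc <- 3 * params$nCodons - Sanc
  truth <- list(omega = params$omega, kappa = params$kappa, t = params$t,
                n_codons = params$nCodons,
                syn_events = synEv, nonsyn_events = nonEv,
                events_a = la$events, events_b = lb$events,
                ks_true = if (Sanc > 0) synEv / Sanc else NA_real_,
                ka_true = if (Nanc > 0) nonEv / Nanc else NA_real_)
  list(cdsA = paste(tab$codons[la$idx], collapse = ""),
       cdsB = paste(tab$codons[lb$idx], collapse = ""),
       truth = truth)
}

#' Expected Ks per unit branch length under the model
#'
#' Analytic helper for tuning \code{t} to a target Ks: the stationary
#' synonymous fraction of the substitution rate divided by the stationary
#' mean of kappa-weighted synonymous sites per codon.
#'
#' @param params A \code{CodonSimParams} (\code{t} ignored).
#' @return Expected Ks for \code{t = 1}.
#' @export
expectedKsPerT <- function(params) {
  tab <- .codonTables()
  Q <- buildRateMatrix(params)
  synRate <- 0
  for (i in which(tab$sense)) {
    sel <- tab$syn[i, ] & !tab$stp[i, ]
    synRate <- synRate + params$pi[i] * sum(Q[i, tab$tgt[i, sel]])
  }
  sv <- .weightedSiteVector(params$kappa, params$pi)
  sBar <- sum(params$pi[tab$sense] * sv[tab$sense])
  synRate / sBar
}

#' Tune the branch length to a target Ks
#'
#' @param params A \code{CodonSimParams}.
#' @param targetKs Desired expected Ks between the two sequences.
#' @return The params with \code{t} set accordingly.
#' @export
tuneBranchLength <- function(params, targetKs) {
  perT <- expectedKsPerT(params)
  if (perT <= 0) stop("model has zero synonymous rate; cannot tune t")
  params$t <- targetKs / perT
  params
}
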