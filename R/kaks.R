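# Pairwise Ka/Ks estimation.
#
# Two estimators are provided. NG86 (Nei & Gojobori 1986) counts
# synonymous site fractions per codon position without weighting,
# averages multi-difference codons over mutational pathways, and corrects
# both proportions with the one-parameter Jukes-Cantor formula. The
# headline YN estimator follows the two-stage logic of Yang & Nielsen
# (2000): kappa is first estimated from fourfold-degenerate and
# nondegenerate site classes with Kimura's two-parameter formulas, sites
# are then counted with each candidate change weighted by kappa
# (transitions) and the stationary frequency of the target codon (F3x4),
# and the proportions are corrected with a two-parameter (K80-style)
# formula.
#
# Changes whose target is a stop codon are excluded from site counting and
# the position renormalized (switchable to the classical
# "count-as-nonsynonymous" convention for cross-checking other
# implementations). Mutational pathways through stop codons are excluded
# with equal weight on the remainder; columns where every path is blocked
# are dropped and tallied.

#' NG86 synonymous/nonsynonymous site counts of one coding sequence
#'
#' Per codon, each position contributes the fraction of synonymous changes
#' among its single-nucleotide changes; with the default stop handling the
#' fraction is taken among non-stop changes so every position still
#' contributes a total weight of 1. \code{S} is the sum of synonymous
#' fractions and \code{N = 3 * codons - S}.
#'
#' @param cds Gap- and ambiguity-free codon string without stop codons.
#' @param stopHandling \code{"exclude"} (renormalize over non-stop
#'   changes) or \code{"nonsynonymous"} (classical divisor of 3).
#' @return Named numeric vector \code{c(S =, N =)}.
#' @examples
#' ng86Sites("TTT")  # S = 1/3: only TTT->TTC is synonymous
#' @export
ng86Sites <- function(cds, stopHandling = c("exclude", "nonsynonymous")) {
  stopHandling <- match.arg(stopHandling)
  idx <- .codonIndices(.normalizeNt(cds))
  sv <- .ng86SiteVector(stopHandling)
  S <- sum(sv[idx])
  c(S = S, N = 3 * length(idx) - S)
}

#' Pathway-averaged difference counts of a codon alignment
#'
#' Columns with one nucleotide difference are classified directly;
#' columns with two or three differences are averaged over all orderings
#' of single-nucleotide steps, excluding orderings that pass through a
#' stop codon (equal weights over the remainder). Columns where every
#' ordering is blocked are excluded and tallied.
#'
#' @param x A [CodonAlignment-class], or the first of two gap-free codon
#'   strings.
#' @param y The second codon string when \code{x} is a string.
#' @return Named numeric vector \code{c(Sd =, Nd =, excluded =)}.
#' @examples
#' ng86Diffs("TTT", "CTC")  # two pathways average to Sd = Nd = 1
#' @export
ng86Diffs <- function(x, y = NULL) {
  idx <- .alignmentIndices(x, y)
  d <- .diffCounts(idx$ia, idx$ib)
  c(Sd = d$sdts + d$sdtv, Nd = d$ndts + d$ndtv, excluded = d$excluded)
}

#' @noRd
.alignmentIndices <- function(x, y = NULL) {
  if (is(x, "CodonAlignment")) return(.comparedIndices(x))
  list(ia = .codonIndices(.normalizeNt(x)),
       ib = .codonIndices(.normalizeNt(y)))
}

# transition/transversion-split pathway-averaged differences
#' @noRd
.diffCounts <- function(ia, ib) {
  if (length(ia) != length(ib)) stop("sequences differ in codon count")
  pt <- .pathTables()
  ok <- pt$ok[cbind(ia, ib)]
  i <- ia[ok]; j <- ib[ok]
  list(sdts = sum(pt$sdts[cbind(i, j)]),
       sdtv = sum(pt$sdtv[cbind(i, j)]),
       ndts = sum(pt$ndts[cbind(i, j)]),
       ndtv = sum(pt$ndtv[cbind(i, j)]),
       excluded = sum(!ok),
       usable = sum(ok))
}

#' Jukes-Cantor distance from a proportion of differences
#'
#' \code{d = -(3/4) ln(1 - (4/3) p)}; \code{NA} with a saturation warning
#' attribute when \code{p >= 3/4}.
#'
#' @param p Proportion(s) of observed differences per site.
#' @return Corrected distance(s); \code{NA} where saturated.
#' @export
jcCorrection <- function(p) {
  ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), NA_real_)
}

# K80-style correction with the transition/transversion split either
# implied by kappa (P = p*kappa/(kappa+2), exactly Jukes-Cantor at
# kappa = 1) or observed (P, Q passed directly)
#' @noRd
.k80Correction <- function(P, Q) {
  a <- 1 - 2 * P - Q
  b <- 1 - 2 * Q
  if (a <= 0 || b <= 0) return(NA_real_)
  -0.5 * log(a) - 0.25 * log(b)
}

#' @noRd
.bucketOf <- function(Sd, Nd) {
  tol <- 1e-12
  if (Sd <= tol && Nd <= tol) "identical"
  else if (Nd <= tol) "syn_only"
  else if (Sd <= tol) "nonsyn_only"
  else "both"
}

#' NG86 Ka/Ks for one alignment
#'
#' Site counts are averaged over the two sequences; proportions
#' \code{pS = Sd/S}, \code{pN = Nd/N} are Jukes-Cantor corrected. The
#' substitution-class bucket is \code{identical}, \code{syn_only},
#' \code{nonsyn_only} or \code{both}; the ratio is only defined for
#' \code{both} (with \code{Ks > 0}), matching the screen's accounting in
#' which single-type pairs carry no ratio.
#'
#' @param alignment A QC-passed [CodonAlignment-class].
#' @param stopHandling See [ng86Sites()].
#' @return A [KaKsResult-class].
#' @export
kaksNG86 <- function(alignment,
                     stopHandling = c("exclude", "nonsynonymous")) {
  stopHandling <- match.arg(stopHandling)
  idx <- .comparedIndices(alignment)
  if (length(idx$ia) == 0L) stop("alignment has no comparable columns")
  sv <- .ng86SiteVector(stopHandling)
  S <- (sum(sv[idx$ia]) + sum(sv[idx$ib])) / 2
  N <- 3 * length(idx$ia) - S
  d <- .diffCounts(idx$ia, idx$ib)
  Sd <- d$sdts + d$sdtv
  Nd <- d$ndts + d$ndtv
  warnings <- character()
  Ks <- if (S > 0) jcCorrection(Sd / S) else NA_real_
  Ka <- if (N > 0) jcCorrection(Nd / N) else NA_real_
  if (S > 0 && is.na(Ks)) warnings <- c(warnings, "Ks saturated")
  if (N > 0 && is.na(Ka)) warnings <- c(warnings, "Ka saturated")
  bucket <- .bucketOf(Sd, Nd)
  ratio <- if (bucket == "both" && !is.na(Ka) && !is.na(Ks) && Ks > 0)
    Ka / Ks else NA_real_
  new("KaKsResult", pairId = alignment@pairId, method = "NG86",
      S = S, N = N, Sd = Sd, Nd = Nd, kappa = 1,
      Ka = Ka, Ks = Ks, ratio = ratio, bucket = bucket,
      excludedColumns = as.integer(d$excluded), warnings = warnings)
}

#' Estimate kappa from degeneracy site classes
#'
#' At codon positions that are fourfold degenerate in both codons and at
#' positions nondegenerate in both, the observed transition proportion
#' \code{P} and transversion proportion \code{Q} give Kimura's
#' \code{A = (1/2) ln(1/(1-2P-Q)) - (1/4) ln(1/(1-2Q))} and
#' \code{B = (1/2) ln(1/(1-2Q))}; the class values are pooled weighted by
#' class site counts and \code{kappa = 2 * A / B} (B estimates twice the
#' per-type transversion rate). Saturated classes are dropped; with no
#' usable information, or with no observed transversions, kappa falls
#' back to 1 with a note. The estimate is floored at 0.1 and capped at 99.
#'
#' @param alignment A QC-passed [CodonAlignment-class].
#' @return kappa (numeric); attribute \code{"note"} carries fallback
#'   warnings, attributes \code{"P"}, \code{"Q"} the pooled proportions.
#' @export
estimateKappa <- function(alignment) {
  idx <- .comparedIndices(alignment)
  tab <- .codonTables()
  stats <- matrix(0, nrow = 2, ncol = 3,
                  dimnames = list(c("f0", "f4"),
                                  c("sites", "ts", "tv")))
  for (p in 1:3) {
    da <- tab$deg[idx$ia, p]
    db <- tab$deg[idx$ib, p]
    cls <- ifelse(da == 0L & db == 0L, "f0",
                  ifelse(da == 3L & db == 3L, "f4", NA))
    sel <- !is.na(cls)
    if (!any(sel)) next
    na <- tab$nt[idx$ia, p][sel]
    nb <- tab$nt[idx$ib, p][sel]
    differ <- na != nb
    isTs <- differ & .isTransition(na, nb)
    for (cl in c("f0", "f4")) {
      m <- cls[sel] == cl
      stats[cl, "sites"] <- stats[cl, "sites"] + sum(m)
      stats[cl, "ts"] <- stats[cl, "ts"] + sum(isTs & m)
      stats[cl, "tv"] <- stats[cl, "tv"] + sum(differ & !isTs & m)
    }
  }
  note <- character()
  A <- B <- w <- numeric()
  for (cl in c("f0", "f4")) {
    L <- stats[cl, "sites"]
    if (L == 0) next
    P <- stats[cl, "ts"] / L
    Q <- stats[cl, "tv"] / L
    a <- 1 - 2 * P - Q
    b <- 1 - 2 * Q
    if (a <= 0 || b <= 0) {
      note <- c(note, paste0("class ", cl, " saturated"))
      next
    }
    A <- c(A, 0.5 * log(1 / a) - 0.25 * log(1 / b))
    B <- c(B, 0.5 * log(1 / b))
    w <- c(w, L)
  }
  if (!length(w) || sum(B * w) == 0) {
    kappa <- 1
    if (!length(w)) note <- c(note, "no usable sites; kappa fallback 1")
    else note <- c(note, "no transversions observed; kappa fallback 1")
  } else {
    Ap <- sum(A * w) / sum(w)
    Bp <- sum(B * w) / sum(w)
    kappa <- 2 * Ap / Bp
    kappa <- min(max(kappa, 0.1), 99)
  }
  structure(kappa, note = note,
            P = sum(stats[, "ts"]) / max(sum(stats[, "sites"]), 1),
            Q = sum(stats[, "tv"]) / max(sum(stats[, "sites"]), 1))
}

#' F3x4 codon frequencies of an alignment
#'
#' Position-specific nucleotide frequencies pooled over both sequences'
#' compared codons; the codon frequency is the product over its three
#' positions, renormalized over sense codons.
#'
#' @param alignment A [CodonAlignment-class].
#' @return Numeric vector of length 64 (stop codons zero) summing to 1
#'   over sense codons.
#' @export
f3x4Frequencies <- function(alignment) {
  idx <- .comparedIndices(alignment)
  tab <- .codonTables()
  freq <- matrix(0, nrow = 3, ncol = 4, dimnames = list(NULL, .BASES))
  for (p in 1:3) {
    nts <- c(tab$nt[idx$ia, p], tab$nt[idx$ib, p])
    cnt <- table(factor(nts, levels = .BASES))
    freq[p, ] <- as.numeric(cnt) / sum(cnt)
  }
  pi64 <- freq[1, tab$nt[, 1]] * freq[2, tab$nt[, 2]] * freq[3, tab$nt[, 3]]
  pi64[!tab$sense] <- 0
  tot <- sum(pi64)
  if (tot <= 0) stop("degenerate frequency table")
  pi64 / tot
}

#' @noRd
.uniformCodonFreqs <- function() {
  tab <- .codonTables()
  pi64 <- ifelse(tab$sense, 1 / sum(tab$sense), 0)
  pi64
}

#' YN00-style Ka/Ks for one alignment
#'
#' Kappa is estimated from degeneracy classes (or forced), codon
#' frequencies by F3x4 (or uniform); sites are counted with each change
#' weighted by kappa and the target codon's frequency, differences are
#' pathway-averaged as in NG86, and Ka/Ks are corrected with a
#' two-parameter formula. With \code{tsSplit = "kappa"} (default) the
#' transition/transversion split entering the correction is the one
#' implied by kappa, which reduces exactly to the Jukes-Cantor correction
#' at kappa = 1 — so forcing \code{kappa = 1, codonFreqs = "uniform"}
#' reproduces NG86 to machine precision. \code{tsSplit = "observed"} uses
#' the pathway-classified transition/transversion difference counts
#' instead.
#'
#' @param alignment A QC-passed [CodonAlignment-class].
#' @param kappa Force a kappa value, or \code{NULL} to estimate.
#' @param codonFreqs \code{"F3x4"}, \code{"uniform"}, or a length-64
#'   frequency vector.
#' @param tsSplit \code{"kappa"} or \code{"observed"}.
#' @param stopHandling See [ng86Sites()].
#' @return A [KaKsResult-class].
#' @export
kaksYN <- function(alignment, kappa = NULL,
                   codonFreqs = c("F3x4", "uniform"),
                   tsSplit = c("kappa", "observed"),
                   stopHandling = c("exclude", "nonsynonymous")) {
  tsSplit <- match.arg(tsSplit)
  stopHandling <- match.arg(stopHandling)
  idx <- .comparedIndices(alignment)
  if (length(idx$ia) == 0L) stop("alignment has no comparable columns")
  warnings <- character()
  if (is.null(kappa)) {
    k <- estimateKappa(alignment)
    warnings <- c(warnings, attr(k, "note"))
    kappa <- as.numeric(k)
  }
  if (is.character(codonFreqs)) {
    codonFreqs <- match.arg(codonFreqs)
    pi64 <- if (codonFreqs == "uniform") .uniformCodonFreqs()
            else f3x4Frequencies(alignment)
  } else {
    pi64 <- codonFreqs
    if (length(pi64) != 64) stop("codonFreqs must have length 64")
  }
  uniform <- isTRUE(all.equal(pi64, .uniformCodonFreqs(), tolerance = 1e-12))
  sv <- if (kappa == 1 && uniform) .ng86SiteVector(stopHandling)
        else .weightedSiteVector(kappa, pi64)
  S <- (sum(sv[idx$ia]) + sum(sv[idx$ib])) / 2
  N <- 3 * length(idx$ia) - S
  d <- .diffCounts(idx$ia, idx$ib)
  Sd <- d$sdts + d$sdtv
  Nd <- d$ndts + d$ndtv
  corr <- function(Dts, Dtv, sites) {
    if (sites <= 0) return(NA_real_)
    p <- (Dts + Dtv) / sites
    if (tsSplit == "kappa") {
      P <- p * kappa / (kappa + 2)
      Q <- p * 2 / (kappa + 2)
    } else {
      P <- Dts / sites
      Q <- Dtv / sites
    }
    .k80Correction(P, Q)
  }
  Ks <- corr(d$sdts, d$sdtv, S)
  Ka <- corr(d$ndts, d$ndtv, N)
  if (S > 0 && is.na(Ks)) warnings <- c(warnings, "Ks saturated")
  if (N > 0 && is.na(Ka)) warnings <- c(warnings, "Ka saturated")
  bucket <- .bucketOf(Sd, Nd)
  ratio <- if (bucket == "both" && !is.na(Ka) && !is.na(Ks) && Ks > 0)
    Ka / Ks else NA_real_
  new("KaKsResult", pairId = alignment@pairId, method = "YN",
      S = S, N = N, Sd = Sd, Nd = Nd, kappa = kappa,
      Ka = Ka, Ks = Ks, ratio = ratio, bucket = bucket,
      excludedColumns = as.integer(d$excluded), warnings = warnings)
}

#' Ka/Ks over a list of alignments as a table
#'
#' @param alignments List of QC-passed \code{CodonAlignment}s.
#' @param method \code{"YN"} or \code{"NG86"}.
#' @param ... Passed to [kaksYN()] or [kaksNG86()].
#' @return \code{data.frame} with one row per alignment (see [asRow()]).
#' @export
kaksTable <- function(alignments, method = c("YN", "NG86"), ...) {
  method <- match.arg(method)
  fun <- if (method == "YN") kaksYN else kaksNG86
  rows <- lapply(alignments, function(a) asRow(fun(a, ...)))
  if (!length(rows))
    return(data.frame(pair_id = character(), method = character(),
                      S = numeric(), N = numeric(), Sd = numeric(),
                      Nd = numeric(), kappa = numeric(), Ka = numeric(),
                      Ks = numeric(), ratio = numeric(),
                      bucket = character(), excluded_columns = integer(),
                      warnings = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Exclude likely paralogs on Ks
#'
#' Removes results whose defined \code{Ks} strictly exceeds \code{ksMax}
#' (default 0.1; a pair at exactly 0.1 is retained). Results with
#' undefined Ks are kept.
#'
#' @param results \code{data.frame} from [kaksTable()].
#' @param ksMax Ks exclusion threshold.
#' @return Retained rows; removed rows in attribute \code{"removed"}.
#' @export
filterParalogs <- function(results, ksMax = 0.1) {
  drop <- !is.na(results$Ks) & results$Ks > ksMax
  out <- results[!drop, , drop = FALSE]
  attr(out, "removed") <- results[drop, , drop = FALSE]
  out
}

#' Classify a pair on its Ka/Ks ratio
#'
#' \code{ratio > 1} is \code{strong} (strong positive selection),
#' \code{0.5 < ratio <= 1} is \code{candidate}, \code{ratio <= 0.5} is
#' \code{non_candidate}; pairs without a defined ratio are
#' \code{unclassifiable}.
#'
#' @param x A \code{KaKsResult}, or a numeric vector of ratios (\code{NA}
#'   allowed).
#' @param strongCut,candidateCut The two thresholds.
#' @return Character vector of classes.
#' @examples
#' classifyCandidate(c(1.7284, 0.5062, 0.1452, NA))
#' @export
classifyCandidate <- function(x, strongCut = 1, candidateCut = 0.5) {
  ratio <- if (is(x, "KaKsResult")) x@ratio else as.numeric(x)
  ifelse(is.na(ratio), "unclassifiable",
         ifelse(ratio > strongCut, "strong",
                ifelse(ratio > candidateCut, "candidate",
                       "non_candidate")))
}

#' Tally substitution-class buckets
#'
#' @param results \code{data.frame} with a \code{bucket} column.
#' @return Named integer vector over
#'   \code{identical, syn_only, nonsyn_only, both}.
#' @export
bucketCounts <- function(results) {
  lv <- c("identical", "syn_only", "nonsyn_only", "both")
  out <- table(factor(results$bucket, levels = lv))
  setNames(as.integer(out), lv)
}
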