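---
title: "Methods: a pairwise Ka/Ks screen for positive selection between two transcriptomes"
author: "kaksScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a pairwise Ka/Ks screen for positive selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kaksScreen)
```

# The problem

Given the assembled transcript sets of two closely related species — the
motivating setting is a pair of frog species from contrasting elevations —
the screen asks which protein-coding genes show an excess of
amino-acid-changing substitutions since the species diverged. The summary
statistic is the ratio of nonsynonymous substitutions per nonsynonymous
site (Ka, also written dN) to synonymous substitutions per synonymous
site (Ks, dS). Under neutrality Ka/Ks is 1; purifying selection drives it
below 1; a ratio above 1 is evidence of positive selection, and ratios
between 0.5 and 1 are treated as weaker candidate signal.

The pipeline has five stages, each usable on its own:

1. **Orthology** — six-frame translated Smith-Waterman search between the
   two transcript sets (BLOSUM62, affine gaps), best hit per transcript
   pair over all 36 frame combinations, a bit-score threshold of 300, and
   reciprocal best hits (RBH). Splice-variant redundancy is collapsed so
   each reference gene contributes one pair.
2. **Coding sequence extraction** — from the supplied annotation
   (reference-aligned coding coordinates) where available, otherwise the
   longest predicted open reading frame, stop-to-stop in any of six
   frames, kept only when strictly longer than 300 nt.
3. **Codon alignment** — the two coding sequences are aligned as proteins
   (global, BLOSUM62, gap open 10 / extend 1) and back-translated so each
   amino-acid column is a codon or a whole-codon gap. Pairs with
   unexpected stop codons, more than 5% ambiguous (N-containing) columns,
   or fewer than 200 aligned bp (300 bp for ORF-predicted pairs) are
   discarded; all thresholds are strict in the directions their wording
   implies (198 bp fails, a 300 nt ORF is not "longer than 300 bp").
4. **Ka/Ks estimation** — described below; pairs with Ks above 0.1 are
   then excluded as likely paralogs (0.1 itself is retained), and the
   rest are classified: ratio > 1 `strong`, 0.5 < ratio <= 1 `candidate`,
   otherwise `non_candidate`. Pairs whose ratio is undefined are
   `unclassifiable`.
5. **GO screening** — mean Ka/Ks per GO term over terms with at least 10
   orthologs, a level-3 category-distribution comparison of candidate vs
   non-candidate genes, and a two-step a-priori screen against
   hypoxia/oxygen-binding terms and against UV/reactive-oxygen/metabolism
   terms.

# The estimators

## NG86

The counting estimator of Nei and Gojobori (1986) serves as the package's
oracle method. Per codon, each of the three positions contributes the
fraction of its single-nucleotide changes that are synonymous; summing
gives the synonymous site count S, and N = 3·codons − S. Mutations whose
target is a stop codon are excluded and the position renormalized over
the remaining changes (a configuration switch restores the classical
count-as-nonsynonymous convention for cross-checking other
implementations). Site counts are averaged over the two sequences.

Differences are counted per aligned codon column. Columns that differ at
one position are classified directly; columns with two or three
differences are averaged over all orderings of single-nucleotide steps,
with orderings that pass through a stop codon excluded and equal weight
placed on the remainder. Columns where every ordering is blocked are
dropped and tallied. Proportions pS = Sd/S and pN = Nd/N are corrected
with the one-parameter Jukes-Cantor formula d = −(3/4)·ln(1 − 4p/3),
which saturates (reported as undefined) at p ≥ 3/4.

## The YN-style estimator

The headline estimator follows the two-stage logic of Yang and Nielsen
(2000). First kappa, the transition/transversion rate ratio, is estimated
from two site classes computed on both codons of each column: positions
fourfold degenerate in both codons (approximately neutral) and positions
nondegenerate in both. Within each class the transition proportion P and
transversion proportion Q give Kimura's

A = (1/2)·ln(1/(1 − 2P − Q)) − (1/4)·ln(1/(1 − 2Q)),
B = (1/2)·ln(1/(1 − 2Q)),

pooled across classes with site-count weights; kappa = 2·A/B because B
estimates twice the per-type transversion rate. Saturated classes are
dropped; with no transversions (or no usable sites) kappa falls back to 1
with a warning, and the estimate is floored at 0.1 and capped at 99.

Sites are then recounted with each candidate change weighted by kappa
(transitions) times the stationary frequency of the target codon, with
frequencies from F3x4 — position-specific nucleotide frequencies pooled
over both sequences. Differences are the same pathway-averaged counts as
NG86. Ka and Ks are corrected with a two-parameter (K80-style) formula.

**A design choice worth spelling out.** The transition/transversion split
entering the correction is, by default, the one implied by the estimated
kappa: P = p·kappa/(kappa + 2) and Q = p·2/(kappa + 2). At kappa = 1 this
is algebraically identical to Jukes-Cantor, so forcing kappa = 1 with
uniform frequencies reproduces NG86 *exactly* — the degenerate limit is
an identity rather than an approximation, which makes the relationship
between the two estimators testable to machine precision. The alternative
of using the observed per-class transition/transversion difference
proportions is available as `tsSplit = "observed"`; at the divergences
this screen targets (Ks around 0.04) the corrections are a few percent of
the proportions and the two variants differ negligibly, but only the
kappa-implied split has the exact NG86 limit.

Substitution-class buckets follow the screen's accounting: `identical`
(no differences), `syn_only`/`nonsyn_only` (one type only), `both`. A
ratio is reported only for `both` pairs with Ks > 0; single-type pairs
carry no ratio, matching how the source accounting treats them.

## What "the YN model" does not include here

The estimator deliberately omits the iterative refinement and
model-averaging extensions found in some Ka/Ks calculators. Fidelity is
enforced instead by properties: exact agreement with exhaustive
enumeration for the counting core, the exact NG86 limit, and parameter
recovery under the generating model (below). Maximum-likelihood codon
models, sliding windows and branch/site models are out of scope.

# The translated search

tblastx-style search is implemented as exhaustive local alignment of all
six query frame translations against all six subject frame translations —
correctness over speed at desk scale; there is no seeding heuristic to
tune or to miss. Raw Smith-Waterman scores convert to bits with fixed
gapped Karlin-Altschul constants (lambda = 0.267, K = 0.041, the standard
gapped BLOSUM62 values), so the conventional bit-score-300 threshold
applies unchanged. The threshold is applied before best-hit selection:
sub-threshold hits are invisible to the RBH stage. "Best hit" is the
highest single local alignment bit score, not a sum over HSPs. Bit-score
ties break by higher identity fraction, then lexicographically smaller
subject id, making best hits unique and the whole stage deterministic.
Stop codons in a translation score like the rarest mismatches (the
BLOSUM62 `*` row), which effectively confines good alignments to open
frames without any special-casing.

With sequences of a few hundred codons this exhaustive search is the
pipeline's dominant cost; the compiled kernel computes score-only
dynamic programming for all frame pairs and revisits only reported hits
for alignment statistics. Because local alignment scores are symmetric,
the reverse-direction hit table is derived by transposition rather than
recomputed.

# The simulator

Validation needs data with known truth, so the package generates ortholog
pairs under a Goldman-Yang-style codon substitution model: the rate from
codon i to j is zero unless they differ at exactly one position and j is
a sense codon, and otherwise proportional to the stationary frequency of
j, times kappa for transitions and omega for nonsynonymous changes. The
matrix is scaled so one unit of branch length is one expected substitution
per codon. An ancestor is drawn from the stationary distribution and each
lineage evolves for t/2 by per-site jump chains (exponential waiting
times) — exact simulation, so realized synonymous/nonsynonymous event
counts in the truth record are event counts, not approximations. The
branch-length convention (t = total path length between the two tips, in
substitutions per codon) matters for interpreting recovery tolerances and
is echoed into fixture metadata.

`tuneBranchLength()` solves for t analytically from a target Ks: the
stationary synonymous fraction of the substitution rate divided by the
stationary mean of weighted synonymous sites per codon.

## Fixture composition

`fixtureSpec()` defaults describe the validation conditions used
throughout the package:

| parameter | default | meaning |
|---|---|---|
| `nOrthologPairs` | 200 | one-to-one ortholog pairs |
| `nStrong` / `omegaStrong` / `tStrong` | 10 / 2 / 0.25 | planted positive selection; t = 0.25 per codon gives roughly 50 substitutions per 200-codon pair and Ks safely below the paralog cut |
| `omegaBackground` / `targetKsBackground` | 0.1 / 0.04 | strong purifying selection at the divergence the source screen reports (mean Ks ≈ 0.04) |
| `nParalogDecoys` / `paralogTargetKs` | 10 / 0.2 | deep pairs above the Ks = 0.1 exclusion; realized truth Ks is verified > 0.1 before emission |
| `nSpliceVariants` | 5 | genes with an exon-skipped (40-codon) second isoform in both species, sharing the reference gene and an overlapping reference interval |
| `nNoncoding` | 20 | random transcripts verified to carry no ORF over 300 nt |
| `nUnannotated` | 10 | background pairs left without annotation, exercising the ORF path |
| `nCodons` | 200 | CDS length; at ~99% protein identity this sits comfortably above the 300-bit search threshold |
| `utrLength` | 50 | UTRs on both sides, built from stop triplets (forward- and reverse-strand stops) with 1–2 random spacer nucleotides so stop phases drift through all frames |

Transcripts are stored reverse-complemented with probability 0.2 to
exercise strand handling. All randomness flows from the single spec seed;
identical spec and seed give byte-identical outputs.

What the generator does *not* emulate: indels within coding sequence
(alignments of simulated pairs are gapless, so alignment-accuracy errors
are absent from recovery tests), rate heterogeneity across sites or
genes, biased codon usage (uniform sense-codon frequencies by default),
assembly artifacts, and sequencing error. Passing recovery tests
therefore validates the estimators and the pipeline logic, not robustness
to misassembly. One realism note: uniform-codon coding sequence quite
often contains a second stop-free frame longer than 300 nt, so ORF
extraction for unannotated transcripts occasionally picks the wrong
frame in one species — such pairs align poorly, inflate Ks, and are
swept out by the paralog filter, the same failure-and-remedy path real
data takes.

# Validation properties

The test suite asserts, among others:

- exact agreement of NG86 site counts (all 61 sense codons) and
  pathway-averaged difference counts (1,000 random codon pairs, enriched
  for 2- and 3-difference columns) with an independent brute-force
  enumeration written directly against the genetic code;
- the exact NG86 limit of the YN estimator (100 simulated pairs, maximum
  deviation below 1e-9);
- recovery of omega across the grid {0.1, 0.5, 1, 2} (kappa = 2, t tuned
  to Ks ≈ 0.04, 200 pairs × 500 codons per point): mean estimated ratio
  within 15% relative error and strictly monotone in the truth;
- kappa recovery within [1.7, 2.3] from 10,000 fourfold-degenerate sites
  simulated under a kappa = 2 two-parameter model at t = 0.2;
- classification of the published fourteen-candidate table ratios into
  the expected classes, with the low-ratio comparators staying below the
  candidate cut;
- end-to-end recovery on the default fixture: at least 9 of 10 planted
  omega = 2 genes called `strong`, all 10 paralog decoys removed at the
  Ks filter, all 5 splice variants collapsed, no noncoding transcript in
  any pair;
- bucket/QC accounting on a hand-built 12-pair toy set, and GO level,
  term-mean, rollup and screen arithmetic on a toy ontology, both against
  hand-computed values.

Problem sizes (200 pairs per grid point, a 200-gene fixture, 10,000 sites
for kappa) were chosen once as the smallest sizes at which binomial noise
is clearly inside the stated tolerances; they are the package's
validation conditions, not tuning knobs.

# Numerical and degenerate-input choices

- Saturation: any correction whose logarithm argument is non-positive
  yields an undefined (NA) estimate with a reason recorded; undefined Ks
  never passes the paralog filter's "defined and greater than" test, so
  saturated pairs are retained for inspection rather than silently
  dropped there.
- `estimateKappa` with no observed transversions falls back to 1 (with a
  note) rather than the cap, following the stated rule for the
  no-information case.
- Zero-frequency codons under F3x4 (a nucleotide absent at a position):
  site weighting falls back to unweighted counts at positions whose
  weight mass is zero.
- Ambiguous (N-containing) and gap columns are excluded from every count;
  the ambiguity QC threshold (5% of ungapped columns) is configurable.
- Ties: ORF ties break by frame order +1, +2, +3, −1, −2, −3 then smaller
  start; hit ties by identity then subject id; collapse ties by total CDS
  length then pair id. Every stage is deterministic given the seed.
- A trailing stop codon on an annotated CDS is trimmed (annotations often
  include the terminator); any remaining stop is treated as unexpected
  and fails QC.

# Interfaces and scope

The package is driven from R: `runSimulate()` writes a fixture's
FASTA/TSV artifacts, `runScreen()` executes the full pipeline from files
or in-memory objects and returns a `ScreenReport` with per-stage
accounting, and every stage (`translatedSearch()`, `reciprocalBestHits()`,
`alignCodonPair()`, `kaksYN()`, `termMeanRatio()`, ...) is exported for
standalone use; `scripts/acceptance.R` recomputes the headline validation
quantities from the installed package. A shell-subcommand wrapper was
considered and not built — the intended users work in R, and the exported
functions plus the script cover the orchestration surface. BLAST
execution, database downloads, read cleaning, assembly, GO enrichment
p-values and ML codon models are out of scope; annotation and GO tables
are inputs.

The a-priori screen lists ship as plain TSV under `inst/extdata` —
the hypoxia/oxygen list and the poikilotherm list cover the functional
categories the screen targets (response to hypoxia, oxygen binding,
response to UV, glutathione metabolism, oxidative-stress response, ATP
catabolism, peroxisome organization, protein catabolism) and are meant to
be replaced by the user's own curated lists when available.

# Known limitations

- Pairwise counting estimators are biased at high divergence; the screen
  is designed for closely related species (Ks well below saturation), and
  the paralog filter at Ks > 0.1 doubles as a guard against the regime
  where the corrections degrade.
- The mean of per-pair Ka/Ks ratios is slightly inflated by noise in the
  denominator (a few percent at Ks ≈ 0.04 with 500 codons); recovery
  tolerances account for this.
- GO "level" is the minimum is_a depth (part_of ignored by default,
  configurable via the relations argument); other tools count levels
  differently, so cross-tool level-3 comparisons need care.
- The RBH stage assumes one-to-one orthology; lineage-specific
  duplications surviving the Ks filter would appear as a single
  best-scoring pair, not be flagged.
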