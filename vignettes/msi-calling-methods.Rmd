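---
title: "Detecting microsatellite instability from tumour/normal repeat-length profiles"
author: "msisweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting microsatellite instability from tumour/normal repeat-length profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msisweep)
```

## The problem

Microsatellites (MS) are tandem repeats of 1-4 bp units, abundant across
the genome. In tumours with deficient mismatch repair, DNA polymerase
slippage at these tracts goes uncorrected and the tract length mutates at
high rate — microsatellite instability (MSI). Clinically, MSI-high (MSI-H)
status predicts response to immune checkpoint therapy, so detecting it
from sequencing data that is collected anyway is valuable.

msisweep implements the full analysis stack: a reference catalogue of MS
tracts; a per-locus tumour/normal caller that compares intra-read repeat
length distributions; frameshift classification of coding events; cohort
recurrence and enrichment statistics; and an MSI-status classifier with
conformal confidence estimates. A slippage-data simulator with known
ground truth drives validation end to end.

## Repeat cataloguing

`find_repeats()` reports maximal perfect tandem tracts of primitive units
(1-4 nt), each tract exactly once at its minimal period, with the unit
canonicalised to its lexicographically smallest rotation. Coordinates are
0-based half-open throughout; BED-like TSVs are the on-disk form. We chose
perfect tracts (no mismatch tolerance) for determinism and testability;
the scanner is verified against a brute-force enumerator that extends
every (position, unit-size) pair maximally.

Two floors are available. The plain length floor (`min_len`, default 6 bp)
is the natural reading of a "6-60 bp" tract window. Reference catalogues
are instead built with a *score* floor (`min_score = 6`): a tract must
contain at least 6 positions that match the position one unit earlier,
i.e. length >= unit length + 6. On perfect tracts this is exactly the
Sputnik match score. The mitochondrial genome fixes the calibration: with
the score floor the hg19 chrM sequence yields 31 loci (10 mono-, 2 di-,
11 tri- and 8 tetranucleotides), and no single-mismatch tolerance is
needed to reproduce that catalogue. With the plain 6 bp floor chrM yields
434 tracts, so the score floor is clearly the operative definition for
catalogue construction; both modes are exposed.

Annotation assigns each locus one region label with precedence
coding > utr5 > utr3 > intronic > intergenic, attaches the
lexicographically first overlapping gene id, and removes loci straddling
an internal exon boundary (splice sites have undetermined genomic
coordinates across isoforms; the boundary window is 0 bp — only tracts
that properly straddle the coordinate are dropped). Overlapping tracts of
different periods are resolved by keeping the longer tract (ties: smaller
start), so catalogue rows never overlap.

## Event calling

For each catalogue locus, spanning reads are re-scanned with the same
repeat detector at a 5 bp intra-read floor (tri- and tetranucleotide
tracts additionally need two full units to have a defined period), and a
read contributes its intra-read tract length only when the tract's unit
matches the locus and the 2 bp flanks on both sides equal the reference
flanks. Truncated, contracted-below-floor and flank-mismatched reads are
discounted. The mapping-quality floor defaults to MAPQ >= 20, the
conventional uniqueness threshold. When one read carries several tracts
of the same unit with matching flanks, the tract closest to the expected
locus offset within the read is used.

Tumour and normal length distributions at a locus are compared with the
two-sample Kolmogorov-Smirnov statistic on the merged integer support.
Loci need at least 5 tumour and 5 normal spanning reads; per-sample
Benjamini-Hochberg adjustment is applied across the tested loci and
events are called at FDR < 0.05. Per-sample adjustment matches per-genome
event counting; a raw-p mode is available for callers that adjust across
a cohort instead.

**p-values under ties.** Integer lengths tie constantly, and with ties
the asymptotic KS p-value is *conservative*: the attainable values of D
are coarser than the continuous approximation assumes, so true positives
near the decision boundary are lost. In our Monte-Carlo verification at
depth 40 and somatic fraction 0.5, asymptotic-only calling recovered
roughly 78% of planted unstable loci, while the exact conditional
permutation distribution of D given the pooled tie pattern
(`stats::psmirnov`) recovered ~98% with zero false calls in the same
runs. The default (`p_method = "hybrid"`) therefore computes the
asymptotic p first and replaces it with the exact conditional p whenever
the screen falls below 0.2. Because the substitution happens only when
the already-conservative screen is small, the reported values remain
valid p-values; an asymptotic-only mode is retained.

**Frameshift rule.** For a significant coding event, the candidate tumour
alleles are the tumour mode plus the second-most-frequent tumour length
when supported by at least 20% of tumour reads. Shifts are measured
against the normal mode. The event is a frameshift when *any* candidate
shift is non-zero and not a multiple of three; a zero shift contributes
no class on its own, so classification can rest entirely on the second
allele. Mode ties break towards the reference tract length, then to the
shorter length — a deterministic rule that favours the germline
configuration.

## Cohort statistics

Recurrence tables count, per locus and sample group, the samples carrying
an event (ties in the ranking break by locus id). Tumour-type enrichment
and MSI-H specificity use one-tailed Fisher's exact tests (enrichment
direction); chromatin-state enrichment uses the two-tailed test, with
each locus assigned to the state overlapping its start coordinate (tracts
are at most 60 bp, so straddles are rare and the assignment is
unambiguous). When several epigenome maps are supplied, per-state overlap
percentages are averaged across maps before testing. Region bias
(coding / 5'UTR / 3'UTR) is tested per sample against the catalogue
composition with separate one-tailed tests for enrichment and depletion.
All Fisher p-values are validated against hypergeometric tail summation
to 1e-10. MSI-H specificity ranking uses raw p (BH q is reported
alongside); tumour types with fewer than five samples trigger a warning.

## MSI status prediction

Each sample is encoded by binary per-gene event indicators (genes with at
least one event in the cohort) plus one total-event count, in fixed
column order. Near-zero-variance features are removed with the
conventional thresholds (frequency ratio > 19 and unique-value fraction
< 10%), remaining features are z-scored, and a 100-tree random forest is
fit, with mtry tuned over {sqrt(d), d/10, d/4, d/2} by stratified 10-fold
cross-validated balanced accuracy. MSI-L samples train as MSS by default
(they group with MSS in practice); a flag excludes them instead.

Mondrian (label-conditional) conformal prediction supplies per-sample
confidence. Calibration lists are built from out-of-fold vote fractions:
for class c, the sorted votes-for-c of training samples whose true label
is c. Crucially, the calibration folds are fully nested — the
near-zero-variance filter and scaling are refit inside each calibration
fold and held-out samples are transformed with that fold's record —
because calibration votes computed with preprocessing fit on all training
data are systematically optimistic, and the resulting conformal p-values
anti-conserve (we measured class-conditional error about twice the
nominal level before nesting; nested calibration restored validity at
every tested significance level).

For a test sample with vote fraction v for class c and calibration list
L, the default (standard) p-value is the smoothed rank
p = (#\{a in L : a <= v\} + 1) / (|L| + 1), and the class enters the
prediction set when p > epsilon. A sample can therefore be called MSI-H,
MSS, *both* (the model cannot discriminate) or *none* (the sample is
outside the model's applicability domain); raising the confidence level
1 - epsilon can only grow the uncertain set. A "literal" convention
(p = #\{a in L : a > v\} / |L|) is also provided: it is the verbatim
reading of one published description of the procedure, in which
calibration votes *above* the test vote count towards inclusion. The two
conventions disagree about the direction of conformity, the standard
scheme is the one with finite-sample validity guarantees, and the output
records which convention produced it.

## The simulator and what it does (not) show

`simulate_reference()` plants perfect repeats between rejection-checked
repeat-free spacers, so the scanner's output on the synthetic contig
equals the truth catalogue exactly. `simulate_tallies()` models each read
as: template allele (the somatically shifted allele with probability
purity x somatic fraction in tumour reads at unstable loci, else
germline), then PCR stutter with probability 0.05 per read, deviation a
whole number of repeat units (1 + geometric(0.5) units, contraction with
probability 0.7 — slippage favours contractions), floored at the
detection limit in unit-sized steps. Defaults: depth Poisson(40), purity
1.0. Cohorts mix MSI-H-like samples (Poisson mean 120 unstable loci of a
600-locus catalogue) with MSS-like samples (mean 2), 25% MSI-H, 800
samples — chosen to mirror the strong separation between MSI-H and MSS
event counts seen in real exome cohorts while staying cheap enough to
simulate repeatedly. `simulate_reads()` realises tallies as perfectly
aligned single-end 100 bp SAM reads whose context is the locus's own
flanking sequence extended with repeat-free filler, so each read tallies
at exactly one locus and the tally -> SAM -> tally round trip is an
identity.

The simulator emulates slippage statistics, not sequencing: no
substitution errors, no quality modelling, no alignment artefacts, no
paired ends, homozygous germline alleles by default (a heterozygous
stress mode exists for the mode-based frameshift rule). Passing tests
therefore demonstrate the statistical machinery — calibration of the KS
test under the stutter null, power at given depth/purity, conformal
validity — not robustness to mapping artefacts or capture bias in real
BAM files.

Problem sizes used by the packaged analyses: the default cohort (800
samples x 600 loci), a 200-locus reference for caller operating
characteristics (50 all-null replicates; depth 10/25/50 and somatic
fraction 0.1/0.3/0.5 grids at 200 planted loci per cell), and 1,000
random sequences for scanner/oracle equivalence. These sizes give
binomial standard errors comfortably inside the margins asserted by the
tests.

## Numerical and degenerate-input choices

* Zero-read Poisson draws yield empty tallies; empty tallies are input
  errors for the KS test and the frameshift rule.
* KS D is computed on the merged integer support with cumulative sums; no
  continuity correction is applied to D itself.
* Exact conditional KS p-values evaluate P(D >= d) via the conditional
  CDF at d - 1e-9 (the distribution of D is discrete).
* The +1-smoothed conformal p-value guarantees p > 0, so epsilon = 0
  always yields the full prediction set.
* Catalogue overlap resolution and all rankings use deterministic
  tie-breaks (documented above), so identical inputs give byte-identical
  output files.
* One pipeline seed controls fold assignment and forest randomness;
  per-sample simulator seeds derive deterministically from the master
  seed.

## Known limitations

Perfect-tract scanning will fragment interrupted repeats that a
mismatch-tolerant scanner would merge; tracts longer than 60 bp and units
of 5+ bp are out of scope. The caller assumes matched normals and does
not estimate purity. The exact conditional KS p-value conditions on the
observed tie pattern, which is standard but not unique. Conformal
validity is class-conditional and marginal over samples; it does not
guarantee per-subgroup coverage.
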