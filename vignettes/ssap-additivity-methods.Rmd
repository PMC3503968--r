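---
title: "Scoring TE insertion-polymorphism dynamics in allopolyploids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring TE insertion-polymorphism dynamics in allopolyploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssapdyn)
```

## The problem

Sequence-specific amplified polymorphism (SSAP) fingerprints anchor an
AFLP-like PCR in the terminus of a transposable element (TE), so each band
marks one insertion junction and is scored dominantly: present (1) or
absent (0) per accession.  In an allopolyploid complex — here modelled on
*Nicotiana* section *Repandae*, formed some 4.5 My ago from ancestors of
*N. sylvestris* (maternal, "SYL") and *N. obtusifolia* (paternal, "TRI"),
with polyploid taxa *N. nudicaulis* ("NUD"), *N. repanda* ("REP") and the
Revillagigedo-Islands species ("ISL") — a polyploid genome is expected to
be *additive*: its band profile should be the union ("sum") of its two
progenitors' profiles.  Departures from additivity are informative about
genome restructuring: **missing** bands are parental insertions no longer
detected, **new** bands are insertions absent from both progenitors.

`ssapdyn` implements this analysis as a reusable pipeline: band
classification, additivity-deviation scoring, sharing-category partitions
across polyploid taxa, parental-origin attribution of losses,
dominant-marker diversity estimation, the accompanying test procedures,
and NeighborNet split networks — plus a synthetic-data generator so the
whole chain is testable without access to raw gel scores (which were never
deposited for the original survey).

## Band classification and deviation scoring

Presence at the *taxon* level is defined as presence in **at least one
accession** of the taxon; no frequency threshold is applied.  This is the
only definition under which multi-accession taxa have a well-defined
profile to "sum", and it matches how the reference tables count shared
bands.  Each locus gets one parental status — `shared_parental`,
`maternal_specific`, `paternal_specific`, or `absent_in_parents` — and,
per polyploid taxon, one label relative to the predicted additive profile
(the union of the two diploid taxon profiles): `additive_present`,
`missing`, `new`, or `absent_everywhere`.  Loci absent from every
accession can arise when subsetting matrices; they are retained (so locus
indices stay stable) but flagged and ignored by every count.

Non-additive bands are partitioned into **sharing categories**: the unique
non-empty subset of polyploid taxa in which a band is new (respectively
missing).  With three polyploid taxa there are 7 categories, reported
all-three first, then pairs, then singletons; the implementation supports
general k (2^k − 1 categories).

Percentage conventions follow the reference tables exactly, and they are
deliberately asymmetric because that is how the printed tables are
arithmetically constructed: in the new-band block the overall percentage
is relative to the family's parental total while per-taxon and category
percentages are relative to the family's overall new count; in the
lost-band block the overall *and* per-taxon percentages are relative to
the parental total and only category percentages are relative to the
overall lost count.

Two points the source material leaves open, decided here:

* **Deviation proportions.**  The printed per-taxon deviation proportions
  use a denominator that cannot be reconstructed from any printed count
  combination we tested.  The package therefore defines and reports its
  own deviation proportion, (new + missing) / (parental total + new), and
  never asserts equality with those printed cells (they ship as a
  reference fixture only).
* **Origin of losses.**  Bands present in both progenitors cannot be
  attributed to either parent when lost, so the paternal/maternal loss
  ratio is computed over parent-specific bands only; shared-parental
  losses are counted and reported separately.

## Reproducing the printed tables

The packaged fixtures transcribe the printed count tables verbatim,
including percentages.  `reproduceTables()` recomputes every derivable
cell with exact arithmetic, rounds half-up at the printed precision
(half-up, not banker's rounding, is the dominant pattern of the tables)
and compares cell by cell.  Six cells do not match any rounding of the
underlying ratio (apparent truncation or typesetting slips, e.g. a shared
percentage printed 15.1 where the ratio is 15.15, or an overall "106"
where the ratio is 106.7), and one all-families cell is internally
inconsistent with its own row and column sums (a per-taxon count printed
82 where both sums give 84).  These are whitelisted with annotations;
every other cell must match, and the test suite fails if any does not.

```{r tables}
rt <- reproduceTables()
rt$totals
nrow(rt$unexplained_mismatches)   # 0: everything off-whitelist matches
subset(rt$comparison, whitelisted)[, c("table_id", "te", "cell",
                                       "computed", "printed")]
```

The published one-way ANOVA on sharing-category distributions is
reproduced by a construction the counts themselves dictate: per family,
category counts divided by the family's overall non-additive count give 7
proportions per category; a fixed-effects ANOVA with category as the
factor (7 groups × 7 families) then matches the printed between-group sum
of squares to three decimals and both F statistics within 0.2%:

```{r anova}
sharingCategoryAnova(loadCountFixture("table5_new"))$anova
sharingCategoryAnova(loadCountFixture("table5_lost"))$anova
```

## Diversity for dominant markers

With full selfing (F_IS = 1) every individual is homozygous, so the
probability of the band-absence phenotype *equals* the null-allele
frequency q — the dominant-marker likelihood collapses to a plain
binomial.  The package makes this reduction explicit rather than porting
a general Lynch–Milligan-style correction: under a Beta(a, b) prior the
posterior is Beta(a + n_absent, b + n − n_absent) with mean
(n_absent + a)/(n + a + b), strictly inside (0, 1).  For F_IS < 1 the
absence phenotype has probability q² + F_IS·q(1 − q) and the posterior
mean is obtained by numerical integration.  The prior is fitted per taxon
and TE family by the method of moments on the observed absence fractions
(loci monomorphic for presence contribute 0), falling back to the uniform
prior when the moment fit is degenerate (zero variance, variance at or
above m(1 − m), or a non-positive parameter).

Nei's gene diversity is reported as expected heterozygosity 2q̂(1 − q̂)
per locus, averaged over loci, with the among-locus SE — the convention
of standard dominant-marker software even though F_IS = 1 implies no
actual heterozygotes; the output records this.  How the original survey
computed between-taxon significance for these quantities is not stated,
so the package exposes the SE and leaves comparisons to the caller.

## Test procedures

All test procedures are implemented in the package and checked against
independent oracles (enumeration, closed forms, and the base-R fits) in
the test suite:

* Yates-corrected chi-square for 2×2 tables and for goodness of fit to a
  fixed ratio, with per-cell correction max(0, |o − e| − ½).  "One-sided"
  p-values follow the direction-gated halving convention used by common
  statistical GUIs: half the two-sided p when the observed direction
  matches the alternative, otherwise one minus that half.
* One-sided Fisher exact tests (hypergeometric tails).
* Wilson score intervals (the single-proportion method Newcombe
  recommends).
* Holm step-down correction — "sequential Bonferroni" — with adjusted
  p-values capped at 1.
* One-way fixed-effects ANOVA with Tukey–Kramer HSD comparisons via the
  studentized-range distribution.
* Mantel tests with simultaneous row/column permutations, the identity
  included in the reference set (so p ≥ 1/(nPerm + 1)); exact enumeration
  is available up to 8 taxa.

The printed chi-square statistics accompanying the diploid band table are
*not* asserted anywhere: no standard 2×2 construction we could build from
the printed counts reproduces them, so `diploidSpecificTests()` reports
the two defensible layouts (specific vs shared within taxa; specific vs
the rest of the family total) side by side without claiming either.

## NeighborNet split networks

Distances are uncorrected P (fraction of differing loci).  The circular
ordering is obtained by the published NeighborNet agglomeration:
neighbor-joining-style Q selection on cluster-averaged distances, node
selection on the mixed set with the chosen clusters exploded, and 3→2
node reductions with the standard 2/3–1/3 weighting.  Tie-breaks, which
the published method leaves unspecified, are fixed to the smallest node
index, and the returned cycle is canonicalised (first taxon leading,
mirror-fixed) so output is deterministic.  Split weights are estimated by
nonnegative least squares over all n(n − 1)/2 circular splits against the
input distances (active-set NNLS via `pracma::lsqnonneg`); zero-weight
splits are dropped.  On additive tree metrics the result *is* the tree —
split set equal to the tree's bipartitions with weights equal to branch
lengths — and on circular-decomposable input the fitted distances
reproduce the input to 1e−8; both properties are enforced in the tests.

Bootstrap support resamples loci with replacement; the support of a split
is the fraction of replicates whose network contains the same accession
bipartition.  The "single diagram at 95% confidence" is implemented as a
per-split support filter with the threshold as a parameter (default
0.95); the more elaborate confidence-network construction of some viewers
is a different object and is deliberately not claimed.  Planar (equal
angle) drawing is out of scope — networks are exported as
SplitsTree-compatible NEXUS (`TAXA` + `SPLITS` blocks with cycle,
weights, and confidences) for downstream viewers.

## The synthetic-data generator

The generator emulates the structure of the study data so that every
pipeline stage has ground truth: two diploid progenitor taxa with shared
and taxon-specific insertions; a polyploid ancestor carrying their union;
a ((REP, ISL), NUD) subtree with five branches (ancestral, early-diverging
terminal, inner, and two late terminals); per-branch whole-locus band
losses; and per-branch Poisson gains of brand-new loci, with a burst
multiplier on the ancestral branch (the genomic-shock scenario).  Losses
among parent-specific bands choose a paternal-origin band with
probability β (the loss bias), so β is exactly recoverable from the
attributable missing bands.  Gains never recreate lost loci, because an
SSAP fragment is a locus-specific junction.

Within-taxon segregation draws a presence-allele frequency per locus and
taxon from a Beta distribution; under F_IS = 1 each accession is a
homozygous carrier with that probability.  Carrier counts are sampled
from a zero-truncated binomial — a band only exists in a dataset when
somebody carries it — which keeps taxon-level presence identical to the
generating band sets.  Two consequences matter for interpreting tests:
the no-event limit (all loss rates and gain means zero) is *exactly*
additive end to end, and deviation counts on simulated data reflect only
logged events, never sampling noise.  Real data differ in precisely this
respect (a segregating band can evade a small sample), as well as in gel
artefacts such as co-migrating fragments and size homoplasy, none of
which are modelled; passing tests therefore demonstrate correctness of
the scoring arithmetic, not robustness to scoring error.

Default parameters were chosen once to mirror the study conditions:
per-family ancestral locus counts equal to the published parental band
structure of the seven TE families; accessions per taxon 4/6/5/6/4
(SYL/TRI/NUD/REP/ISL) as in the original sampling; branch loss rates
(0.40 ancestral, 0.10/0.06/0.12/0.08 later) and a paternal bias of 0.6
giving overall loss and origin patterns in the qualitative range of the
published tables; presence-frequency Beta(4, 1) (mean 0.8, so bands are
common but segregate visibly); per-family gain means and burst
multipliers scaled so families map onto the observed contrasts (gain-rich
TS/Tnt2-like, loss-dominated Au/TRIM-like).

The recovery study used in the acceptance checks runs 100 seeded
replicates with β = 0.8, 1200 parent-specific loci and loss rates chosen
so each replicate yields on the order of 550 attributable losses; the
Wilson 95% interval around the estimated paternal fraction must cover the
true β in at least 93 replicates.

## Problem sizes and numerical choices

The shipped tests run the table reproduction on the full fixtures
(exact), NeighborNet recovery on 5–8-taxon metrics, bootstrap checks at
10–25 replicates on 5–10 accessions, the Fisher enumeration over all 2×2
tables with totals ≤ 12, and the recovery study at the sizes above —
sizes at which every oracle is exact or near-exact and the whole suite
completes in about a minute.  Zero-weight splits are cut at 1e−9;
fixture comparisons use exact rationals before the final half-up
rounding; Mantel p-values use an epsilon of 1e−12 when comparing
correlations to avoid tie artefacts.

## Known limitations

* Matrix-level results of the original survey (network figures, per-taxon
  diversity values, per-taxon origin percentages) are not numerically
  reproducible by anyone: the raw 594-band matrices were never deposited.
  Everything derivable from the printed counts is reproduced; the rest is
  covered by property-based tests on synthetic data.
* The deviation-proportion and diploid chi-square constructions of the
  original tables are ambiguous, as described above; the package reports
  defined alternatives rather than guessing.
* Whether deviations arose in the polyploids or in the diploid lineages
  after divergence cannot be distinguished by this design, and the
  package makes no attempt to.
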