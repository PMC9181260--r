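---
title: "Methods: maternal-lineage tracing, heteroplasmy calling and the resampled breeding-value comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: maternal-lineage tracing, heteroplasmy calling and the resampled breeding-value comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitolineage)
```

This package supports the analysis of a maternally inherited mitochondrial
point mutation segregating in a closed cattle population: which animals
carry it (pedigree), whether it is homoplasmic (sequencing base counts),
what it does to the protein (mitochondrial genetic code), where its
homologue sits in another species' mitogenome (alignment), how to assay it
(in-silico PCR), and whether carriers differ in breeding value from the rest
of the population (resampling). This vignette explains the models and the
design choices behind each step; the package's tests compute every empirical
claim made here.

## Maternal lineages in a pedigree

mtDNA passes from dam to offspring without recombination, so the carrier
set of a homoplasmic mitochondrial variant is a *matriline*: all animals
reachable from one founder cow through dam links. We define a maternal
lineage as the connected component of the dam-edge-only graph —
equivalently, the set of animals sharing a matriline founder. The
definition makes lineage membership well-defined for every animal (each has
at most one dam, so the founder is unique) and makes the lineages a
partition of the pedigree; both properties are tested.

Two parsing decisions matter in practice. First, herd-book extracts are
ragged: parents are routinely referenced without having rows of their own.
`read_pedigree()` materialises such parents as founder records with unknown
fields rather than rejecting the file (`complete_pedigree()`), because
discarding those rows would silently truncate matrilines. Second, unknown
parents are coded inconsistently (`0`, empty, `NA`, `.`); the accepted
codes are configurable through `pedigree_dialect()`, as are column names
and day-first dates. Cycles in the joint sire/dam graph, duplicate ids,
male animals referenced as dams, and cull dates before birth are hard
errors at load time — every downstream computation assumes these
invariants.

Carrier inference (`infer_carriers()`) encodes strict homoplasmic maternal
transmission: one genotyped mutant implicates its whole matriline as
expected carriers. A genotyped wildtype inside that set is reported as a
`conflict`, never silently reconciled — a conflict means either a genotyping
error, a pedigree error or a de-novo event, and all three deserve eyes.

Ages are measured in completed calendar months (the month completes when
the end date's day-of-month reaches the birth day-of-month), not as day
counts divided by 365.25. This is the convention in which herd-book
longevity is quoted ("15 years and 7 months"), and it makes the arithmetic
exactly reproducible from dates alone.

## Homoplasmy and heteroplasmy from base counts

A site's evidence is a pileup: counts of A, C, G, T among the reads
covering it. `classify_site()` calls the site heteroplasmic when the
second-most-frequent base clears three thresholds simultaneously:

* minor fraction ≥ `min_minor_fraction` (default 0.02),
* minor count ≥ `min_minor_count` (default 5 reads),
* depth ≥ `min_depth` (default 50 reads).

Below the depth floor no call is made at all (`no_call`). The defaults are
deliberately permissive relative to a biologically meaningful mixture — a
minor allele near 37% of several thousand reads is orders of magnitude
above all three bars — while staying above the per-base error rate of
short-read data (~10⁻³), so an error-only site at high depth has a minor
fraction near 0.0003 and is called homoplasmic. The classification is
monotone in the thresholds (tightening them never creates heteroplasmy),
which is property-tested. Ties in the major/minor ranking are broken
lexicographically and flagged, for determinism. A homoplasmic site whose
major base differs from the reference is a fixed substitution — the
situation at a site where every mtDNA copy carries the alternate allele.

The pileup simulator draws the minor count from a binomial with success
probability `f(1−e) + (1−f)e/3` (a true-minor read survives error, or a
true-major read is miscalled into the minor base) and scatters further
errors onto the two remaining bases. It emulates one site at one depth; it
does not model mapping bias, strand asymmetry, or contamination from
nuclear copies of mtDNA, so passing recovery tests says nothing about
those failure modes of real data.

## Coding consequences under the vertebrate mitochondrial code

`translate_mito()` embeds the vertebrate mitochondrial genetic code as an
explicit 64-entry table (TGA→Trp, AGA/AGG→stop, ATA→Met); the test suite
audits all 64 codons against an independent reference table. Codon
arithmetic in `annotate_consequence()` is plain integer geometry: with the
0-based within-CDS offset `o`, the codon index is `o %/% 3 + 1` and the
within-codon position `o %% 3 + 1`. Genes on the light strand are handled
by reading the reverse complement from the feature's end, with all reported
coordinates remaining on the plus strand. All coordinates in the package
are 1-based inclusive; BED input is converted on read.

## Coordinate mapping and in-silico PCR

Positions are carried between two mitogenomes by one global pairwise
alignment with affine gaps (defaults: match +2, mismatch −3, gap open 8,
gap extend 1 — conservative scores that favour compact homology blocks for
sequences around 80% identical). The mapped coordinate is whatever sits in
the query's alignment column; queries landing on a gap return the nearest
upstream coordinate flagged `gap_adjacent` rather than guessing. On
identical sequences the map is the identity at every position
(property-tested).

`insilico_pcr()` finds the forward primer on the plus strand and the
reverse complement of the reverse primer downstream of it, each within a
configurable mismatch budget (default 0, no indels). Product length runs
from the forward primer's 5′ end through the reverse primer's 5′ end,
inclusive — the gel-band length. Circular genomes are searched on a doubled
sequence so products may span the origin; away from the origin the circular
and linearised results agree, which is tested. An absent primer site is an
explicit empty result, not an error, because "no product" is an assay
outcome.

## The resampled breeding-value comparison

The carrier group is small (tens of animals) and its breeding values are
not independent (the animals are maternally related), so a parametric
two-sample test is not attempted. Instead the observed carrier mean for a
trait is placed against the distribution of means of `reps` random
subsets, of the carrier group's size, drawn from the non-carrier animals:

* subsets are drawn **without replacement** within a replicate (a "sample
  of k animals" is read as a set of distinct animals; with-replacement
  sampling is available as an option and recorded in the report);
* the credibility interval is the **equal-tailed** interval of the
  replicate means at the configured level (default 95%), using the
  linear-interpolation empirical quantile definition, with inclusive
  boundaries (a mean exactly on a bound is "within");
* `tail_fraction` reports `(count beyond the observed mean + 1)/(reps+1)`,
  the standard resampling correction that avoids zero estimates; it is
  descriptive, not a p-value;
* each trait receives an independently spawned sub-seed derived
  deterministically from the master seed, so a multi-trait report is
  reproducible bit-for-bit from one integer.

The study-scale defaults are `k = 44`, `reps = 10000`, `level = 0.95`
against a non-carrier pool of several thousand animals.

Two calibration facts are worth stating precisely. If the "carrier" vector
is itself a subset of the non-carrier pool, its mean is one more
exchangeable draw from the null and the within-interval rate is the nominal
level; the tests verify ≈95%. If instead carrier and non-carrier values are
drawn i.i.d. from a common distribution, the within-interval rate is
systematically *below* the nominal level, for two reasons the procedure
itself creates: the interval is centred on the finite non-carrier sample
(the carrier-mean-minus-centre variance is σ²(1/k + 1/n), not σ²/k), and
without-replacement resampling shrinks the null spread by the
finite-population factor √(1−k/n). The resulting coverage is approximately
2Φ(1.96·√(1−k/n)/√(1+k/n))−1: about 0.93 for a pool of 500, and about 0.95
for a pool the size of the study's non-carrier group (n = 3578, where both
corrections are negligible). The acceptance checks compute both regimes;
at the study scale the procedure is calibrated, and the small-pool deficit
is a property of the method users should know about before applying it to
small comparison groups. Relatedness among the carriers is *not* modelled:
the comparison is marginal, and a carrier group of close relatives has an
effective sample size below k, making the interval anti-conservative in a
way no resampling of the non-carriers can repair.

## The synthetic-data generator

The generator exists so that every stage is testable without herd data.
`simulate_pedigree()` founds `n_founder_dams` maternal lineages in the
first year of the range (default 1997–2020, the recorded window the
analysis targets), then simulates calving year by year: each cow aged 2–12
produces a Poisson(0.35) number of calves, calf sex is Bernoulli(0.5), and
sires are drawn among contemporaneous males. The Poisson calving model and
the reproductive window are the package's own choices of a simple, slowly
growing herd — with these defaults ten founders grow to a few hundred
animals over 24 years; the offspring distribution, age structure and
selection of a real breeding program are deliberately not emulated.
Haplotypes are copied dam-to-calf, so the generator enforces exactly the
faithful homoplasmic transmission the carrier inference assumes — the
transmission invariant (every animal's haplotype equals its matriline
founder's) is asserted across seeds, and conflicts are impossible by
construction. A per-year, per-lineage birth ledger is returned as ground
truth for the annual statistics.

`simulate_bv()` draws non-carrier values i.i.d. Gaussian per trait
(defaults: six conformation-type traits, mean 0, sd 1, group sizes
3578/44) and shifts the carrier mean by a configurable per-trait amount.
Gaussianity is an idealisation of estimated breeding values — real BVs have
shrinkage-induced heteroscedasticity and family structure the simulator
omits — so power results transfer to real data only approximately.

## Problem sizes and numerical choices

The test suite and the acceptance script scale simulations to desk size:
100 random pedigrees of up to 200 animals for the matriline oracle,
exhaustive subset enumeration up to n = 12, k = 4 for the resampling
oracle, 2000 rounds of 2000 replicates for coverage calibration, 300 seeds
for heteroplasmy recovery at depth 6287, and 16.3 kb synthetic genomes
(one global alignment of that size takes seconds). Reference-scale checks
(the published primer pair, the +231 coordinate offset, the codon-65
geometry) run against synthetic constructions that embed the documented
geometry, labelled as such, because the real reference sequences are not
bundled with the package.

All randomness flows from explicit integer seeds; every report echoes its
seed and a digest of the analytic configuration. Quantiles are R type 7
everywhere; dates are ISO-8601; coordinates 1-based inclusive. Degenerate
inputs are handled by explicit policy rather than accident: zero-depth
pileups are `no_call`, a zero-birth year has an undefined (not zero)
lineage proportion, an absent primer site is an empty product table, a
missing maternal path is `NULL`, and `k` equal to the pool size collapses
every replicate mean to the pool mean.
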