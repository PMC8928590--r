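---
title: "Interval statistics for single-sperm CNV call sets: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interval statistics for single-sperm CNV call sets: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spermcnv)
library(dplyr)
```

## What this package computes

`spermcnv` implements the downstream interval statistics used when
structural-variant (SV) calls from single-sperm sequencing are compared
against a diploid family trio and against the repeat landscape of the
genome. The upstream steps — whole-genome amplification, alignment, and SV
calling with a LUMPY-style caller — are out of scope: the package consumes
the caller's VCF output and a handful of standard annotation tables
(chromosome sizes, RepeatMasker-style repeats, pairwise segmental-duplication
fragments, GFF3 genes, term-to-gene maps).

Five analysis stages are provided, mirroring how such a study is reported:

1. **Filtering** (`filter_by_length()`, `filter_by_support()`,
   `tally_by_group()`): quality filters on raw calls and per-group summary
   tallies.
2. **Segmental-duplication summarisation** (`summarize_segdup_pairs()`,
   `nonredundant_fragments()`, `merge_regions()`,
   `per_chromosome_summary()`).
3. **Repeat-content enrichment** (`repeat_content()`,
   `permutation_test()`, `enrichment_folds()`).
4. **Chromosome-arm positional analysis** (`relative_positions()`,
   `bin_arm_distribution()`, `terminal_enrichment_test()`).
5. **Multi-group sharing and annotation** (`cluster_events()`,
   `remove_singletons()`, `venn_summary()`, `annotate_features()`,
   `fisher_enrichment()`).

A synthetic-data generator (`sim_config()`, `simulate_study()`) produces
every input the pipeline needs with *planted*, parameterised structure, so
each stage can be validated against known truth without sequencing data.

All coordinates inside the package are 0-based half-open; conversion to the
1-based conventions of VCF and GRanges happens only at format boundaries.
Interval algebra is delegated to IRanges/GenomicRanges behind the
tibble-in/tibble-out surface.

## The filtering model

Copy-number variants are taken to span 50 bp to 5 Mb; DEL and DUP calls
outside that (inclusive) range are discarded, while INV and BND records are
exempt from the length rule but still tallied. The support filter encodes a
two-signal rule tied to the sample's fold coverage `c`: a call is kept when
one read signal clears `0.75 * c` **and** the other clears a small absolute
floor,

```
(PE > 0.75 c  AND  SR > 1)   or   (SR > 0.75 c  AND  PE > 3).
```

Comparisons are strict and the coverage threshold is real-valued — at
`c = 4` the primary signal must exceed 3, and at `c = 4.4` it must exceed
3.3. The natural-language statement of this rule admits other readings
(e.g. requiring the *sum* of signals, or tying both signals to coverage);
we adopt the either-signal-primary reading above and expose every constant
in `filter_policy()`, so an alternative reading is a one-argument change.
Filters are idempotent and commute, which the tests assert.

## The random-region permutation test

For a target region set (CNVs, SegDups, or their flanks) and each repeat
class, three metrics are computed against the merged target footprint:
`Length%` (repeat bp overlapped per target bp, as a percentage), `Count/Mb`
(overlapping repeat features per Mb of footprint), and `Average Length`
(overlapped bp per overlapping feature). Enrichment folds divide each
metric by its genome-wide value.

Significance comes from a Monte-Carlo null: `n_iter` (default 1000) random
region sets are drawn *matched to the target's region count and length
mean/SD* — lengths from a normal distribution truncated below at 50 bp,
chromosome chosen proportional to length, start uniform so the region fits —
and the metric is recomputed each time. The empirical enrichment p is the
fraction of null values *strictly greater* than the observation; ties
therefore favour significance, and the smallest attainable p is 0, reported
as `< 1/n_iter`. A depletion p (strictly less) accompanies every enrichment
p, and a `(k+1)/(n+1)` correction is available but off by default so that
the headline p has the frequency interpretation above.

Design choices worth stating:

* **Distributional length matching, not resampling.** The null draws new
  lengths from the fitted truncated normal rather than permuting the
  observed lengths; a `length_mode = "resample"` switch exists for
  sensitivity analysis. Matching on (mean, SD) is the procedure being
  emulated; with strongly skewed length distributions the two modes can
  differ, which is precisely what the switch is for.
* **Null regions may overlap each other** and are not constrained away from
  the target; an `exclude` set (e.g. assembly gaps) is supported but empty
  by default.
* **Plug-in calibration.** Because the null matches *estimated* target
  moments, the test is only asymptotically exact; at 200 targets-from-null
  repetitions with `n_iter = 200` we observe type-I error at the nominal
  0.05 level within a few percentage points, varying by a couple of points
  with the random seed — adequate for an empirical-p screen with a 0.05
  threshold, and the acceptance suite pins it to [0.03, 0.07] under a fixed
  seed.
* **Reproducibility.** Iteration `i` uses a sub-seed derived from the master
  seed, so results do not depend on evaluation order.

Within a repeat class, overlapping annotation features are unioned before
any accounting; standard RepeatMasker tables are already disjoint within a
class, so this is normally a no-op but makes the bp and count semantics
unambiguous for arbitrary inputs.

## Flanks and fold decay

`flank_regions()` builds fixed-width flanks (defaults 5 kb and 20 kb)
clipped at chromosome ends, with the merged footprint of *all* input
regions subtracted, so a flank never covers a region — including a
neighbouring one. Flank metrics use the merged flank footprint, consistent
with the target's footprint denominators. When repeat co-location is local
to the regions themselves, folds decay from the target through 5 kb to
20 kb flanks toward the genome average; the acceptance suite reproduces
this qualitative decay on synthetic data with planted satellite
co-location.

## The terminal (subtelomeric) enrichment test

Cattle autosomes are acrocentric, so each chromosome is treated as a single
arm and an event's position is summarised as `midpoint / chromosome length`
in [0, 1). The arm profile bins these fractions into twenty half-open 5%
bins.

The terminal test asks whether events concentrate near chromosome ends.
Per chromosome, the terminal 5% at each end is *excluded* (in real data
these strips harbour assembly artefacts and unusually high read-count
outlier bins near telomeres); the two **end windows** are the next 5 Mb
inward on each side; the **interior** is everything between. End-window and
interior event densities (events/Mb — the windows differ in size, so raw
counts would be confounded) are compared across chromosomes with a paired
two-sided Wilcoxon signed-rank test; an unpaired rank-sum over the same
densities is reported as a secondary statistic, and a raw-count mode
exists. When every paired difference is zero the p is 1 by convention.
Chromosomes shorter than twice (terminal strip + window) are skipped with a
warning.

The windowing phrase "5 Mb after removing the terminal 5%" admits a second
reading (ends = terminal 5 Mb, with the terminal 5% removed from the
comparison only); we use the first reading — excluded strip, then scored
window — as the default because it keeps the excluded artefact region out
of *both* sides of the comparison.

## Sharing analysis

Cross-sample event matching is not specified by any caller, so the package
makes it explicit: same-type DEL/DUP calls are clustered by single linkage
under either a ≥ 1 bp overlap rule (default) or a 50% reciprocal-overlap
rule, the standard alternatives in the CNV literature. Clusters with exactly
one member call are **singletons** — an event seen once in one sample — and
are removed before sharing analysis; a DEL seen in two sperm cells of the
same bull occurred twice and is kept. Venn categories over the three groups
(bull 1 sperm, bull 2 sperm, bull 1 trio) are assigned from the member
calls' group labels, and the summary reports event percentages alongside
length percentages under *both* length conventions — the union footprint of
member calls and the sum of member lengths — because published totals
rarely say which convention they used. The trio group comprises the three
diploid family members (proband, sire, dam), which is what allows a
trio-only event to recur and survive singleton removal.

Gene and term enrichment is deliberately generic: `annotate_features()`
intersects regions with any GFF3-derived feature table (≥ 1 bp), and
`fisher_enrichment()` takes any term-to-gene map (GO, KEGG, QTL traits) and
runs a two-sided Fisher exact test per term with Benjamini–Hochberg
adjustment across terms. No live databases are bundled or queried, which
keeps the procedure testable offline; the Fisher p is cross-checked in the
tests against exhaustive hypergeometric enumeration for every 2×2 table
with n ≤ 20.

## The synthetic-data generator

`simulate_study()` emulates the study design the statistics were built for:

* a 29-autosome genome with lengths uniform on 40–160 Mb;
* repeat classes (LINE, SINE, LTR, DNA, Satellite) placed non-overlapping
  within class at configurable genome densities (defaults 10/5/3/2/2%,
  log-normal feature lengths around class-typical means), realising each
  requested density essentially exactly by construction;
* pairwise SegDup fragments with truncated-normal identities and Bernoulli
  orientation;
* two sperm panels (8 and 6 cells at 4× — the deep-sequenced subset of a
  sperm study) plus the diploid trio at 40×/10×/20×;
* shared DEL/DUP events following a configurable Venn sharing profile,
  whose default is the 433-event three-group profile
  (18/45/158/18/123/56/15); per-sample singleton calls; INV events and BND
  breakend mate pairs;
* planted placement biases: with probability `satellite_colocation_prob`
  an event midpoint lands inside a Satellite repeat, and with probability
  `distal_bias` it lands in a distal band at a chromosome end;
* PE/SR support counts drawn so that a configurable fraction of calls
  passes the support filter at the sample's coverage, with the planted
  flag recorded in the truth table.

Three generator choices deserve explanation:

* **Event lengths** are log-uniform on the configured range, 50 bp–5 Mb by
  default so both filter bounds are exercised. The demo configuration
  (`inst/extdata/demo_config.yaml`) narrows this to 50 bp–50 kb, consistent
  with the observed scale of shared sperm CNVs (433 events totalling
  ~1.7 Mb, i.e. ~4 kb on average); without that narrowing, hundreds of
  multi-megabase events cannot coexist on a toy genome.
* **The distal band is 15% of each chromosome end**, wider than the 5%
  strip the terminal test excludes. A planted "distal" event is meant to
  model subtelomeric concentration that the test can detect; if the band
  equalled the excluded strip, planted events would fall entirely inside
  the region the test ignores and no positional method could see them.
  With the 15% band, planted mass covers the excluded strip *and* the
  scored end windows on chromosomes of the default size.
* **Distinct same-type events never overlap.** Placement rejects proposals
  overlapping an already-placed DEL (resp. DUP) event, so at zero
  coordinate jitter the overlap-clustering stage recovers the planted Venn
  categories exactly — which is what makes exact end-to-end sharing checks
  possible. A configurable `jitter` shifts member calls to stress the
  overlap rule instead.

What the generator does *not* model: amplification (MALBAC) coverage
non-uniformity, read-level data, aneuploidy, GC/mappability structure, and
reference artefacts. Passing tests on synthetic data therefore validate the
*statistics* — filters, interval algebra, the permutation machinery, the
positional test, sharing and enrichment — not the upstream caller's
behaviour on real single-cell data.

## Determinism and numerical conventions

One master seed drives a run; every module and iteration derives an
independent sub-seed keyed by a label, so adding samples or stages does not
shift earlier draws, and identical configurations are byte-identical across
runs (the pipeline manifest records config, seed, version and file
checksums). Percentages in summary tables are rounded to 2 decimals —
matching how such tables are printed — while p-values and folds are kept at
full precision. Degenerate inputs are defined, not NaN: empty targets give
zero metrics with a warning, an all-zero paired comparison gives p = 1, and
unplaceable simulation requests abort with a message rather than silently
truncating.

## Problem sizes used in the shipped checks

The packaged test and acceptance runs use deliberately small instances —
toy genomes of 50–180 Mb for the enrichment calibration (200 repetitions at
200 iterations), 50 seeded runs of ~200 planted events for satellite
recovery, 50 + 50 runs of ~1,000 events on a full-size 29-chromosome
genome for the terminal test, and 100 random 200-interval fixtures for the
oracle comparisons. These sizes give the binomial error bounds quoted in
the tests; the same functions run unchanged on full-genome inputs.

## Worked example

```{r example, eval = FALSE}
cfg <- validate_config(system.file("extdata", "demo_config.yaml",
                                   package = "spermcnv"))
res <- run_pipeline(cfg, out_dir = "demo_run")
res$venn          # sharing percentages over the three groups
tidy(res$enrichment)   # repeat-class enrichment with empirical p-values
glance(res$terminal)   # subtelomeric Wilcoxon test
plot_arm_profile(res$arm_profile)
```
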