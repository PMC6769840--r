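---
title: "Methods: maternal CNV discovery from shallow WGS of plasma DNA"
author: "shallowcnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: maternal CNV discovery from shallow WGS of plasma DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shallowcnv)
library(dplyr)
```

## The problem

Non-invasive prenatal testing (NIPT) sequences cell-free DNA from maternal
plasma at very low coverage (around 0.3x, 2x35 bp reads). Most of that DNA
is the mother's own, so a heterozygous maternal copy-number variant (CNV)
appears as a full-amplitude depth shift: in diploid-ratio units (1.0 =
two copies), a single-copy gain is expected at 1.5 and a single-copy loss
at 0.5. At 20 kbp bin resolution this signal is strong enough that CNVs of
600 kbp and larger can be called reliably from data produced for a
completely different purpose, which turns routine NIPT screening into a
population survey of large CNVs.

`shallowcnv` implements that reanalysis pipeline end to end:

1. count unique read starts in fixed 20 kbp bins;
2. filter empty bins and detrend counts against GC content with LOESS;
3. remove shared higher-order artifacts by projecting each sample onto the
   top principal components of a euploid control cohort;
4. mask low-coverage (low-complexity) bins;
5. segment each chromosome's ratio profile with circular binary
   segmentation (CBS) and a permutation test;
6. call segments of at least 600 kbp whose mean ratio deviates by at least
   60% of a single-copy shift;
7. annotate calls against known-variant interval databases and gene
   intervals, and aggregate cohort-level statistics with per-variant
   carrier frequencies.

A synthetic-cohort generator with machine-readable truth sets stands in
for patient data, which are anonymized and undeposited.

## Normalization model

### GC detrending

For one sample, let $RC_{obs,i}$ be the observed count in retained bin $i$
(usable and non-empty), $RC_{fit,i}$ the LOESS prediction of count from
the bin's GC fraction, and $RC_{global}$ the mean observed count over
retained bins. The corrected count is

$$RC_{corr,i} = RC_{obs,i} - (RC_{fit,i} - RC_{global}),$$

i.e. the GC trend is removed additively around the global mean. Two
consequences of the additive form matter downstream:

* A CNV's corrected amplitude is $1 \pm 0.5\,b_i$ (not exactly $1 \pm
  0.5$), where $b_i$ is the local GC bias factor. Under the default
  synthetic bias curve this spreads a single event's internal amplitude by
  up to roughly 0.08 ratio units, which is why segment pruning (below)
  uses a threshold above that scale.
* The fit must not be dragged by the CNV bins themselves. The LOESS is
  therefore fitted with `family = "symmetric"` (Tukey-biweight
  iterations), so the small fraction of copy-shifted bins is downweighted
  automatically. Plain least squares is available via the `family`
  argument; with it, a large event can displace the fitted trend at its
  GC values and distort diploid regions that share those GC values.

Defaults: span 0.3, local-linear (degree 1), at least 30 retained bins
spanning at least two distinct GC values. A degenerate GC distribution is
an error, not a silent pass-through.

### PCA denoising

Euploid control samples are corrected, scaled to their retained-bin mean,
and the top $K$ principal directions of the centred control matrix (over
masked-in bins) form the reference (default $K = 5$; $K$ must be smaller
than the number of controls; $K = 0$ disables the step). A test sample is
scaled the same way, its deviation from the control bin-mean profile is
projected onto the components, and the projection is subtracted.

Two design choices protect real signal:

* components are **never** refitted on the test sample;
* projection coefficients are estimated by least squares over bins
  surviving one round of outlier trimming ($|z| > 3$), so bins carrying a
  genuine copy-number shift (which sit many standard deviations from the
  bulk) do not soak signal into the subtraction. This holds as long as
  shifted bins are a small minority (roughly under 10% of the genome).

After subtraction the control bin means are re-added and the profile is
divided by its masked-in mean, so a euploid sample has mean ratio exactly
1 and a heterozygous event is expected near $1 \pm 0.5$.

Bins whose mean control count falls below 10% of the global mean are
masked as low-complexity regions (threshold configurable).

## Segmentation

CBS treats each chromosome's masked-in ratio sequence as a circle and
finds the arc $(i, j]$ maximizing the two-sample $|t|$ between arc and
complement (pooled variance). The scan is exact and exhaustive
($O(n^2)$ per scan, implemented in C++ with prefix sums); ties — notably
the two complementary arcs of one split, equal up to rounding — resolve
to the smallest $i$, then smallest $j$, with a relative $10^{-10}$
tolerance so floating-point noise cannot flip the choice.

Significance is assessed by permutation: the stretch's values are
shuffled (Fisher-Yates on R's RNG, so everything is reproducible from the
seed), and the split is accepted when $p = (b+1)/(B+1) < \alpha$ with
defaults $B = 10000$, $\alpha = 0.01$. Permutation stops early once the
exceedance count guarantees $p \ge \alpha$; that decision is exact, and
the per-stretch RNG stream is derived from the seed and the stretch
coordinates, so results do not depend on recursion order and lowering
$\alpha$ cannot increase the number of segments. Accepted splits recurse;
a final pruning pass merges adjacent segments whose means differ by less
than 0.1 ratio units.

The pruning default deserves a note: it must sit *above* the within-event
amplitude structure left by additive GC detrending (about half the
regional bias spread, up to ~0.08 under the default synthetic bias curve)
or long events fragment into sub-600 kbp pieces that the length filter
then drops; and it must sit far *below* 0.3, the smallest deviation that
separates diploid from callable segments. 0.1 satisfies both with margin.
Segmentation operates on linear ratio, keeping the calling arithmetic
transparent; masked bins contribute nothing to the statistics but a
segment's genomic span bridges masked gaps in its interior.

## Calling rule

A segment becomes a call when its genomic span is at least 600 kbp
(inclusive — reported call sets include 600 kbp events) and its mean
ratio reaches at least 60% of a single-copy shift: ratio $\ge 1.3$ for
gains, $\le 0.7$ for losses, both inclusive ("at least"). The 60% margin
tolerates fetal-fraction dilution and residual noise without admitting
diploid wobble. Calls inherit segment coordinates unchanged.

## Annotation and cohort aggregation

* **Overlap classes.** For each call, type-compatible database records
  overlapping it are collected; the call is `full` when the union of those
  records covers every base of the call, `partial` when coverage is in
  (0, 1), `none` otherwise. Union coverage is the weakest reading of
  "overlapping in full extent" and is the default; single-record
  containment and reciprocal-overlap definitions are selectable. Type
  matching is on by default; records typed `any` (or untyped) match both.
* **Coding attribution.** Gene intervals are merged before intersection;
  `coding_bp` is the number of call bases in the merged set, so
  overlapping genes count once, and identical calls in different samples
  each count in full. A call is gene-overlapping when `coding_bp > 0`.
* **Variant clustering.** Same-type calls with reciprocal overlap of at
  least 0.5 are joined by single linkage; a cluster's frequency is its
  number of distinct carrier samples divided by the cohort size. The 50%
  reciprocal-overlap convention is the field's usual identity criterion
  and is configurable. Detection events (member calls) and distinct
  carriers are reported separately.
* **Percentages** are printed half-up to 2 decimals (carrier percentage
  to 1 decimal, matching the conventional report format); per-variant
  frequencies to 4 decimals. All derived percentages recompute exactly
  from the integer counts.

## The synthetic cohort generator

The generator emulates the study conditions the pipeline was built for:

* ~0.3x coverage with 35 bp reads binned at 20 kbp, i.e. a default mean
  of 171 unique reads per bin ($0.3 \times 20000 / 35$); Poisson counts
  by default, negative binomial (configurable size) for overdispersed
  cfDNA;
* a smooth, spatially correlated GC track (mean 0.40, sd 0.05,
  ~500 kbp correlation length, mimicking isochore-scale structure) and a
  unimodal quadratic bias curve peaking at GC 0.45 with range
  [0.6, 1.1] — a typical Illumina shape;
* rank-3 shared artifacts: smooth unit-sd bin patterns common to the
  cohort, per-sample standard-normal loadings, applied as
  $\exp(0.01\, \ell^\top p_i)$. The 0.01 scale (~1.7% per-bin log-sd) is
  the magnitude of residual cross-sample structure one sees after GC
  correction, and — more importantly — is the regime in which an additive
  projection can actually remove a multiplicative artifact: at CNV bins
  the ratio is 1.5, so a fraction shift/2 of the artifact survives linear
  removal, and at several times this scale that residual (not the noise)
  becomes the limiting factor for boundary recovery;
* 1% of bins forced to zero coverage and flagged unusable
  (low-complexity stand-ins); implanted events snap to bin boundaries
  (the pipeline's resolution is one bin) at per-variant cohort
  frequencies below 1%, with deterministic carrier counts
  (`round(frequency x n)`) by default so truth sets are exactly
  reproducible.

What the generator does **not** emulate: real isochore GC, mappability
structure, fragment-size selection, fetal fraction, sequencing error, and
within-run batch structure. Passing recovery tests therefore demonstrate
the pipeline's statistical machinery under controlled conditions, not
clinical performance on real cfDNA.

Test and benchmark problem sizes are scaled to what the statistics need
rather than to genome size: recovery experiments use six 20 Mbp
chromosomes (6000 bins), 30 controls, 50 test samples with 0-2 implanted
events of 600-3000 kbp each, and 2000 permutations per split test; the
per-split p-value resolution (1/2001) stays an order of magnitude below
the 0.01 alpha.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere internally (BED
  convention); printed reports are 1-based inclusive.
* A constant stretch has $t = 0$ and never splits; a zero pooled variance
  with unequal means is treated as infinitely significant (sentinel).
* All-empty samples, degenerate GC, $K \ge$ number of controls,
  singular projections, and intervals with `end <= start` are errors with
  informative messages, not silent repairs.
* Calling thresholds are compared with a $10^{-9}$ absolute tolerance so
  literal boundary values (a segment at exactly 1.3) are inclusive under
  floating-point arithmetic.
* Every stochastic step (grid, cohort, permutations) derives its stream
  from an explicit seed; normalization is fully deterministic.

## Known limitations

* The additive GC correction makes event amplitude mildly GC-dependent
  ($1 \pm 0.5 b$); the 60% calling margin absorbs this, but amplitude is
  not a calibrated copy-number estimate.
* Sex chromosomes are out of scope (the pipeline models 22 autosomes);
  so are sub-600 kbp events, mosaicism quantification, and separating
  fetal from maternal events.
* Pathogenicity labels are consumed from the database's `label` column,
  never computed.
* With very strong shared artifacts (several times the default scale),
  the fraction of artifact surviving at CNV bins grows and boundary
  precision degrades before detection does.
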