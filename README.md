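# shallowcnv

Maternal copy-number variant (CNV) discovery from shallow whole-genome
sequencing of cell-free plasma DNA.

Non-invasive prenatal testing (NIPT) sequences maternal plasma DNA at
~0.3x coverage. Because most plasma DNA is maternal, a heterozygous
maternal CNV shifts the normalized read depth by half a copy — in
diploid-ratio units (1.0 = two copies), a single-copy gain sits near 1.5
and a single-copy loss near 0.5. `shallowcnv` turns that byproduct signal
into a population survey of large CNVs: it reimplements, as a tested R
package, the reanalysis pipeline used to screen thousands of NIPT samples
for maternal CNVs of 600 kbp and larger.

The pipeline, per sample:

1. **Binning** — unique read starts counted in fixed 20 kbp bins
   (`bin_read_positions()`), with GC per bin from a reference FASTA
   (`gc_from_fasta()`) or a supplied bin table.
2. **GC correction** — empty bins filtered, then robust LOESS detrending
   of count on GC: `RC_corr = RC_obs − (RC_fit − RC_global)`
   (`loess_gc_correct()`).
3. **PCA denoising** — projection onto the top K principal components of
   a euploid control cohort is subtracted (`fit_pca_reference()`,
   `pca_normalize()`); low-coverage bins are masked
   (`mask_low_coverage_bins()`).
4. **Segmentation** — circular binary segmentation with an exact
   max-arc-t scan (C++) and a permutation test, p = (b+1)/(B+1)
   (`cbs_segment()`, `max_arc_t()`).
5. **Calling** — segments ≥ 600 kbp whose mean ratio reaches at least 60%
   of a single-copy shift (≥ 1.3 or ≤ 0.7, inclusive) become maternal CNV
   calls (`call_cnvs()`; `call_sample()` runs steps 2–5 in one go).
6. **Annotation** — overlap classes (full / partial / none) against
   known-variant records and coding/non-coding attribution against merged
   gene intervals (`classify_overlap()`, `coding_attribution()`).
7. **Cohort summary** — per-variant carrier frequencies via 50%
   reciprocal-overlap single-linkage clustering, counts/percentages by
   type, size and per-chromosome distributions, and the coding-Mbp table
   (`cluster_variants()`, `summarize_cohort()`, with `tidy()`, `glance()`
   and `autoplot()` methods).

A first-class synthetic-cohort generator (`simulation_spec()`,
`simulate_bin_grid()`, `simulate_cohort()`) emulates the study
conditions — 0.3x coverage, GC bias, shared low-rank artifacts,
low-complexity dropout, implanted events with a machine-readable truth
set — and backs the package's recovery benchmarks
(`run_recovery_benchmark()`). See the methods vignette
(`vignettes/shallow-wgs-cnv-calling.Rmd`) for the model, parameter
defaults, and known limitations.

## Worked example

Simulate a small study (two 20 Mbp chromosomes at 0.3x-like coverage),
implant a 1.2 Mbp duplication into one sample, and run the pipeline:

```r
library(shallowcnv)
library(dplyr)

spec <- simulation_spec(n_chromosomes = 2, chromosome_length_bp = 2e7,
                        seed = 11)
grid <- simulate_bin_grid(spec)

controls <- simulate_cohort(grid, spec, n_samples = 20, seed = 12)
ref <- fit_pca_reference(controls$counts, grid, n_components = 3)

event <- tibble(chrom = "chr2", start_bp = 5e6, end_bp = 6.2e6,
                type = "gain", ratio_shift = 0.5)
sample1 <- simulate_sample(grid, spec, events = event,
                           artifact = list(patterns = controls$artifact,
                                           loading = c(1, -0.5, 0.2)),
                           sample_id = "PL0001", seed = 13)

profile <- normalize_profile(sample1, grid, ref)
segments <- cbs_segment(profile, cbs_params(n_permutations = 2000, seed = 14))
call_cnvs(segments)
#> # A tibble: 1 × 9
#>   sample_id chrom start_bp  end_bp type  mean_ratio n_bins length_bp length_kbp
#>   <chr>     <chr>    <dbl>   <dbl> <chr>      <dbl>  <int>     <dbl>      <dbl>
#> 1 PL0001    chr2   5000000 6200000 gain        1.47     57   1200000       1200
```

The implanted event is recovered at its exact boundaries: mean ratio 1.47
(expected 1.5 for a heterozygous gain), 57 masked-in bins spanning the
1200 kbp (three dropout bins inside the event are bridged). Annotation
against a known-variant record and a gene interval:

```r
db <- tibble(chrom = "chr2", start_bp = 4.9e6, end_bp = 6.2e6,
             type = "gain", id = "nsv-like-001")
genes <- tibble(chrom = "chr2", start = 5.5e6, end = 5.8e6, name = "GENE1")
call_cnvs(segments) |>
  classify_overlap(db) |>
  coding_attribution(genes)
#>   chrom type  overlap_class overlap_fraction coding_bp
#> 1 chr2  gain  full                         1    300000
```

The call is fully covered by the database record (`full`, the class used
for "overlapping in full extent") and 300 kbp of it is coding sequence.
`plot_profile(profile, segments)` draws the per-bin ratios with the
segment overlay; `summarize_cohort()` aggregates a cohort's calls.

A command-line wrapper with `simulate`, `normalize`, `segment`, `call`,
`annotate` and `summarize` subcommands is installed at
`inst/cli/shallowcnv.R`.

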