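#' Quadratic GC-bias curve
#'
#' Returns a function mapping GC fraction to a multiplicative coverage bias.
#' The default is a unimodal quadratic peaking near GC 0.45 and clipped below,
#' the typical shape of Illumina shallow-WGS coverage bias.
#'
#' @param peak GC fraction at which coverage is maximal.
#' @param top Bias at the peak.
#' @param floor Minimum bias (curve is clipped here).
#' @param width GC distance from the peak at which the curve reaches `floor`.
#' @return A vectorised function on \[0, 1\] with strictly positive values.
#' @examples
#' curve <- gc_bias_quadratic()
#' curve(c(0.3, 0.45, 0.6))
#' @export
gc_bias_quadratic <- function(peak = 0.45, top = 1.1, floor = 0.6,
                              width = 0.30) {
  stopifnot(top > floor, floor > 0, width > 0)
  a <- (top - floor) / width^2
  function(gc) pmax(floor, top - a * (gc - peak)^2)
}

#' Flat (unit) GC-bias curve
#' @return A function returning 1 for every GC value.
#' @export
gc_bias_flat <- function() {
  function(gc) rep(1, length(gc))
}

#' Simulation specification for a synthetic shallow-WGS cohort
#'
#' Bundles the data-generating assumptions for synthetic plasma-DNA read-count
#' profiles: a genome tiled into fixed-width bins, a mean unique-read count
#' per bin matching ~0.3x coverage with 35 bp reads, a smooth GC-dependent
#' multiplicative bias, shared low-rank cross-sample artifacts, and a fraction
#' of zero-coverage (low-complexity) bins.
#'
#' The default `mean_reads_per_bin` of 171 is the expectation implied by 0.3x
#' coverage of 35 bp reads in a 20 kbp bin (0.3 x 20000 / 35).
#'
#' @param n_chromosomes Number of chromosomes to simulate.
#' @param chromosome_length_bp Length of each chromosome in bp (scalar or one
#'   value per chromosome). A trailing partial bin is dropped.
#' @param bin_size_bp Bin width in bp (default 20000).
#' @param mean_reads_per_bin Expected unique reads per usable bin before bias.
#' @param gc_bias Function mapping GC fraction to multiplicative bias; must be
#'   positive on \[0, 1\]. See [gc_bias_quadratic()].
#' @param gc_mean,gc_sd Centre and spread of the simulated bin GC fractions
#'   (defaults mimic the ~0.40 mean GC of the human genome).
#' @param gc_corr_bins Smoothing window (in bins) of the spatially correlated
#'   GC process.
#' @param artifact_rank Number of shared low-rank artifact components.
#' @param artifact_scale Log-scale magnitude of the shared artifacts.
#' @param dropout_fraction Fraction of bins forced to zero coverage and
#'   flagged unusable (emulating low-complexity regions).
#' @param noise Count noise model: Poisson, or negative binomial for
#'   overdispersed cfDNA counts.
#' @param nb_size Negative-binomial size (inverse dispersion) when
#'   `noise = "nbinom"`.
#' @param seed Integer seed controlling grid simulation.
#' @return An object of class `simulation_spec`.
#' @examples
#' spec <- simulation_spec(n_chromosomes = 1, chromosome_length_bp = 1e6)
#' simulate_bin_grid(spec)
#' @export
simulation_spec <- function(n_chromosomes = 6,
                            chromosome_length_bp = 2e7,
                            bin_size_bp = 20000,
                            mean_reads_per_bin = 171,
                            gc_bias = gc_bias_quadratic(),
                            gc_mean = 0.40,
                            gc_sd = 0.05,
                            gc_corr_bins = 25,
                            artifact_rank = 3,
                            artifact_scale = 0.01,
                            dropout_fraction = 0.01,
                            noise = c("poisson", "nbinom"),
                            nb_size = 50,
                            seed = 1L) {
  noise <- match.arg(noise)
  if (bin_size_bp <= 0) abort("`bin_size_bp` must be positive.")
  if (any(chromosome_length_bp <= 0))
    abort("`chromosome_length_bp` must be positive.")
  if (n_chromosomes < 1) abort("`n_chromosomes` must be at least 1.")
  if (mean_reads_per_bin < 0) abort("`mean_reads_per_bin` must be >= 0.")
  if (dropout_fraction < 0 || dropout_fraction >= 1)
    abort("`dropout_fraction` must be in [0, 1).")
  if (artifact_rank < 0) abort("`artifact_rank` must be >= 0.")
  gtest <- gc_bias(seq(0, 1, by = 0.05))
  if (any(!is.finite(gtest)) || any(gtest <= 0))
    abort("`gc_bias` must evaluate to positive finite values on [0, 1].")
  len <- rep_len(chromosome_length_bp, n_chromosomes)
  structure(
    list(n_chromosomes = n_chromosomes, chromosome_length_bp = len,
         bin_size_bp = bin_size_bp, mean_reads_per_bin = mean_reads_per_bin,
         gc_bias = gc_bias, gc_mean = gc_mean, gc_sd = gc_sd,
         gc_corr_bins = gc_corr_bins, artifact_rank = artifact_rank,
         artifact_scale = artifact_scale,
         dropout_fraction = dropout_fraction, noise = noise,
         nb_size = nb_size, seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat("<simulation_spec>\n")
  cat(sprintf("  genome: %d chromosome(s), %s bp, %d bp bins\n",
              x$n_chromosomes,
              paste(format(x$chromosome_length_bp, big.mark = ","),
                    collapse = "/"),
              x$bin_size_bp))
  cat(sprintf("  coverage: %.1f reads/bin (%s noise), dropout %.2g\n",
              x$mean_reads_per_bin, x$noise, x$dropout_fraction))
  cat(sprintf("  artifacts: rank %d, scale %.3g; seed %d\n",
              x$artifact_rank, x$artifact_scale, x$seed))
  invisible(x)
}

# smooth spatially-correlated GC track for one chromosome
simulate_gc_track <- function(n_bins, gc_mean, gc_sd, window) {
  window <- max(1L, min(as.integer(window), n_bins))
  z <- rnorm(n_bins + 2 * window)
  sm <- stats::filter(z, rep(1 / window, window), sides = 2)
  sm <- as.numeric(sm)[(window + 1):(window + n_bins)]
  s <- sd(sm)
  if (!is.finite(s) || s == 0) s <- 1
  gc <- gc_mean + (sm - mean(sm)) / s * gc_sd
  pmin(0.99, pmax(0.01, gc))
}

#' Simulate a bin grid
#'
#' Tiles each simulated chromosome with fixed-width bins (dropping any partial
#' trailing bin), assigns each bin a GC fraction drawn from a smooth spatially
#' correlated process, and flags a `dropout_fraction` of bins unusable.
#'
#' @param spec A [simulation_spec()].
#' @return A tibble with columns `chrom`, `start`, `end` (0-based half-open),
#'   `gc`, `usable`.
#' @export
simulate_bin_grid <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(derive_seed(spec$seed, 101L), {
    grids <- purrr::map(seq_len(spec$n_chromosomes), function(ci) {
      n_bins <- spec$chromosome_length_bp[ci] %/% spec$bin_size_bp
      if (n_bins < 1)
        abort(sprintf("chromosome %d is shorter than one bin", ci))
      start <- (seq_len(n_bins) - 1) * spec$bin_size_bp
      tibble(
        chrom = sprintf("chr%d", ci),
        start = start,
        end = start + spec$bin_size_bp,
        gc = simulate_gc_track(n_bins, spec$gc_mean, spec$gc_sd,
                               spec$gc_corr_bins),
        usable = TRUE
      )
    })
    grid <- bind_rows(grids)
    if (spec$dropout_fraction > 0) {
      grid$usable <- runif(nrow(grid)) >= spec$dropout_fraction
    }
    grid
  })
}

# validate and bin-snap a set of events for one sample; returns per-bin shift
event_shifts <- function(grid, events, bin_size) {
  shift <- rep(0, nrow(grid))
  if (is.null(events) || nrow(events) == 0) return(shift)
  stopifnot_cols(events, c("chrom", "start_bp", "end_bp", "type",
                           "ratio_shift"), "events")
  if (any(events$end_bp <= events$start_bp))
    abort("events must satisfy end_bp > start_bp")
  bad_sign <- (events$type == "gain" & events$ratio_shift <= 0) |
    (events$type == "loss" & events$ratio_shift >= 0)
  if (any(bad_sign))
    abort("event `type` must be consistent with the sign of `ratio_shift`")
  # snap to bin boundaries (pipeline resolution is one bin)
  ev <- events
  ev$start_bp <- round(ev$start_bp / bin_size) * bin_size
  ev$end_bp <- pmax(ev$start_bp + bin_size,
                    round(ev$end_bp / bin_size) * bin_size)
  for (r in seq_len(nrow(ev))) {
    sel <- grid$chrom == ev$chrom[r] & grid$start >= ev$start_bp[r] &
      grid$end <= ev$end_bp[r]
    if (!any(sel))
      abort(sprintf("event %s:%d-%d lies outside the bin grid",
                    ev$chrom[r], ev$start_bp[r], ev$end_bp[r]))
    clash <- sel & shift != 0 & sign(shift) != sign(ev$ratio_shift[r])
    if (any(clash))
      abort("overlapping events of different type in one sample")
    shift[sel] <- ev$ratio_shift[r]
  }
  shift
}

#' Simulate one sample's bin counts
#'
#' Draws the per-bin unique-read count from a Poisson (or negative binomial)
#' distribution with mean `mean_reads_per_bin * gc_bias(gc) * (1 +
#' ratio_shift) * artifact factor`. Unusable (dropout) bins get count 0.
#' Event boundaries are snapped to bin boundaries.
#'
#' @param grid Bin grid tibble from [simulate_bin_grid()].
#' @param spec A [simulation_spec()].
#' @param events Optional tibble of truth events with columns `chrom`,
#'   `start_bp`, `end_bp`, `type` ("gain"/"loss"), `ratio_shift` (+0.5 = full
#'   single-copy gain in a diploid).
#' @param artifact Optional shared-artifact term: a list with `patterns`
#'   (rank x n_bins matrix) and `loading` (length-rank numeric); the per-bin
#'   multiplicative factor is `exp(artifact_scale * loading %*% patterns)`.
#' @param sample_id Sample identifier stored in the output.
#' @param seed Integer seed (NULL continues the current RNG stream).
#' @return The grid tibble with `sample_id` and `count` columns appended.
#' @export
simulate_sample <- function(grid, spec, events = NULL, artifact = NULL,
                            sample_id = "S1", seed = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  stopifnot_cols(grid, c("chrom", "start", "end", "gc", "usable"), "grid")
  shift <- event_shifts(grid, events, spec$bin_size_bp)
  if (any(1 + shift < 0)) abort("ratio_shift below -1 gives a negative mean")
  mu <- spec$mean_reads_per_bin * spec$gc_bias(grid$gc) * (1 + shift)
  if (!is.null(artifact)) {
    stopifnot(is.matrix(artifact$patterns),
              length(artifact$loading) == nrow(artifact$patterns),
              ncol(artifact$patterns) == nrow(grid))
    lf <- as.numeric(crossprod(artifact$loading, artifact$patterns))
    mu <- mu * exp(spec$artifact_scale * lf)
  }
  mu[!grid$usable] <- 0
  counts <- with_seed(seed, {
    if (spec$noise == "poisson") rpois(length(mu), mu)
    else rnbinom(length(mu), mu = mu, size = spec$nb_size)
  })
  counts[mu == 0] <- 0L
  out <- grid
  out$sample_id <- sample_id
  out$count <- as.integer(counts)
  select(out, "sample_id", "chrom", "start", "end", "gc", "usable", "count")
}

# smooth unit-sd artifact bin patterns shared by a cohort
artifact_patterns <- function(n_bins, rank, window = 50) {
  if (rank == 0) return(matrix(0, nrow = 0, ncol = n_bins))
  t(vapply(seq_len(rank), function(r) {
    p <- simulate_gc_track(n_bins, 0, 1, window)
    (p - mean(p)) / sd(p)
  }, numeric(n_bins)))
}

#' Simulate a cohort of shallow-WGS samples with implanted CNVs
#'
#' Generates `n_samples` count profiles sharing the same bin grid, GC bias and
#' low-rank artifact patterns (sample-specific loadings), implanting each
#' requested variant into a set of carrier samples at its stated cohort
#' frequency. Returns the counts together with a machine-readable truth set.
#'
#' @param grid Bin grid from [simulate_bin_grid()].
#' @param spec A [simulation_spec()].
#' @param n_samples Cohort size (>= 2).
#' @param variants Optional tibble of variants: `chrom`, `start_bp`, `end_bp`,
#'   `type`, `ratio_shift`, `frequency` (per-variant carrier frequency in
#'   \[0, 1\]).
#' @param assignment `"deterministic"` gives each variant exactly
#'   `round(frequency * n_samples)` carriers; `"binomial"` draws each sample
#'   independently.
#' @param seed Integer seed for the whole cohort.
#' @return A list with `counts` (long tibble: one row per sample x bin),
#'   `truth` (tibble of implanted events with `sample_id`), and `artifact`
#'   (the shared patterns, for inspection).
#' @export
simulate_cohort <- function(grid, spec, n_samples, variants = NULL,
                            assignment = c("deterministic", "binomial"),
                            seed = NULL) {
  assignment <- match.arg(assignment)
  if (n_samples < 2) abort("`n_samples` must be at least 2.")
  if (!is.null(variants) && nrow(variants) > 0) {
    stopifnot_cols(variants, c("chrom", "start_bp", "end_bp", "type",
                               "ratio_shift", "frequency"), "variants")
    if (any(variants$frequency > 1) || any(variants$frequency < 0))
      abort("variant `frequency` must lie in [0, 1]")
  }
  seed <- seed %||% spec$seed
  with_seed(derive_seed(seed, 202L), {
    ids <- sprintf("S%04d", seq_len(n_samples))
    patterns <- artifact_patterns(nrow(grid), spec$artifact_rank)
    loadings <- matrix(rnorm(n_samples * spec$artifact_rank),
                       nrow = n_samples)

    truth <- tibble(sample_id = character(), chrom = character(),
                    start_bp = numeric(), end_bp = numeric(),
                    type = character(), ratio_shift = numeric())
    if (!is.null(variants) && nrow(variants) > 0) {
      per_variant <- purrr::map(seq_len(nrow(variants)), function(v) {
        carriers <- if (assignment == "deterministic") {
          k <- round(variants$frequency[v] * n_samples)
          if (k > 0) sample(ids, k) else character()
        } else {
          ids[runif(n_samples) < variants$frequency[v]]
        }
        if (length(carriers) == 0) return(NULL)
        tibble(sample_id = carriers,
               chrom = variants$chrom[v], start_bp = variants$start_bp[v],
               end_bp = variants$end_bp[v], type = variants$type[v],
               ratio_shift = variants$ratio_shift[v])
      })
      truth <- bind_rows(truth, purrr::compact(per_variant))
    }

    counts <- purrr::map(seq_len(n_samples), function(s) {
      ev <- filter(truth, .data$sample_id == ids[s])
      art <- if (spec$artifact_rank > 0)
        list(patterns = patterns, loading = loadings[s, ]) else NULL
      simulate_sample(grid, spec, events = ev, artifact = art,
                      sample_id = ids[s], seed = NULL)
    })
    list(counts = bind_rows(counts),
         truth = arrange(truth, .data$sample_id, .data$chrom,
                         .data$start_bp),
         artifact = patterns)
  })
}
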