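# End-to-end recovery benchmark on synthetic cohorts: simulate controls and
# test samples with implanted single-copy events, run the full pipeline, and
# score detection against the truth set.

# match each truth event to the best same-sample/chrom/type call with
# reciprocal overlap >= min_ro; returns call row index or NA per truth row
match_truth_calls <- function(truth, calls, min_ro = 0.5) {
  vapply(seq_len(nrow(truth)), function(k) {
    tr <- truth[k, ]
    if (nrow(calls) == 0) return(NA_integer_)
    m <- calls$sample_id == tr$sample_id & calls$chrom == tr$chrom &
      calls$type == tr$type
    if (!any(m)) return(NA_integer_)
    w <- pmax(0, pmin(calls$end_bp, tr$end_bp) -
                pmax(calls$start_bp, tr$start_bp))
    ro <- w / pmax(calls$end_bp - calls$start_bp, tr$end_bp - tr$start_bp)
    cand <- which(m & ro >= min_ro)
    if (length(cand) == 0) NA_integer_ else cand[which.max(ro[cand])]
  }, integer(1))
}

#' Recovery benchmark on a simulated cohort
#'
#' Simulates a euploid control cohort and a set of test samples carrying 0-2
#' implanted full single-copy events each (ratio shift plus or minus 0.5,
#' sizes drawn between `event_kbp[1]` and `event_kbp[2]`, bin-aligned, at
#' most one event per chromosome per sample), runs the full pipeline
#' (GC correction, PCA denoising against the simulated controls, CBS,
#' length/amplitude calling), and scores the calls against the truth set.
#'
#' A truth event counts as recovered when a call of the same sample,
#' chromosome and type has reciprocal overlap of at least 0.5 with it; calls
#' matching no truth event are false calls; boundary accuracy is the
#' fraction of recovered events whose called start and end both lie within
#' one bin of the truth.
#'
#' @param spec A [simulation_spec()]; its defaults are the benchmark's
#'   coverage and bias conditions.
#' @param n_controls Euploid samples used to fit the PCA reference.
#' @param n_samples Test samples (events cycle 0, 1, 2 per sample).
#' @param event_kbp Size range of implanted events in kbp.
#' @param n_components PCA components removed.
#' @param params [cbs_params()] for segmentation.
#' @param min_length_kbp,min_fraction Calling thresholds.
#' @param seed Master seed for the whole benchmark.
#' @return A list: `truth`, `calls`, `matched` (call index per truth row),
#'   `sensitivity`, `false_calls_per_genome`, `boundary_within_1bin`
#'   (fraction), `n_truth`, `n_calls`.
#' @examples
#' \donttest{
#' bench <- run_recovery_benchmark(n_samples = 6, seed = 7)
#' bench$sensitivity
#' }
#' @export
run_recovery_benchmark <- function(spec = simulation_spec(),
                                   n_controls = 30, n_samples = 50,
                                   event_kbp = c(600, 3000),
                                   n_components = 5,
                                   params = cbs_params(n_permutations = 2000),
                                   min_length_kbp = 600, min_fraction = 0.6,
                                   seed = 1L) {
  grid <- simulate_bin_grid(spec)
  controls <- simulate_cohort(grid, spec, n_samples = n_controls,
                              seed = derive_seed(seed, 1L))
  ref <- fit_pca_reference(controls$counts, grid,
                           n_components = n_components)

  bin <- spec$bin_size_bp
  chroms <- unique(grid$chrom)
  bins_per_chrom <- table(grid$chrom)[chroms]
  len_lo <- ceiling(event_kbp[1] * 1000 / bin)
  len_hi <- floor(event_kbp[2] * 1000 / bin)

  truth_all <- list()
  calls_all <- list()
  with_seed(derive_seed(seed, 2L), {
    for (i in seq_len(n_samples)) {
      n_ev <- (i - 1) %% 3
      ev <- NULL
      if (n_ev > 0) {
        evc <- sample(chroms, n_ev)
        len_bins <- sample(len_lo:len_hi, n_ev, replace = TRUE)
        nb <- as.integer(bins_per_chrom[evc])
        start_bin <- vapply(seq_len(n_ev), function(e)
          sample(0:(nb[e] - len_bins[e] - 1), 1), numeric(1))
        type <- sample(c("gain", "loss"), n_ev, replace = TRUE)
        ev <- tibble(chrom = evc, start_bp = start_bin * bin,
                     end_bp = (start_bin + len_bins) * bin, type = type,
                     ratio_shift = if_else(type == "gain", 0.5, -0.5))
      }
      sid <- sprintf("T%03d", i)
      art <- if (spec$artifact_rank > 0)
        list(patterns = controls$artifact,
             loading = rnorm(spec$artifact_rank)) else NULL
      sm <- simulate_sample(grid, spec, events = ev, artifact = art,
                            sample_id = sid)
      sample_params <- cbs_params(alpha = params$alpha,
                                  n_permutations = params$n_permutations,
                                  min_seg_bins = params$min_seg_bins,
                                  prune_mean_diff = params$prune_mean_diff,
                                  seed = derive_seed(seed, 3L, i))
      cl <- call_sample(sm, grid, ref, sample_params,
                        min_length_kbp = min_length_kbp,
                        min_fraction = min_fraction)
      if (!is.null(ev)) truth_all[[i]] <- mutate(ev, sample_id = sid)
      if (nrow(cl) > 0) calls_all[[i]] <- cl
    }
  })
  truth <- bind_rows(truth_all)
  calls <- bind_rows(calls_all)
  matched <- match_truth_calls(truth, calls)
  hit <- !is.na(matched)
  b_ok <- if (any(hit)) {
    ds <- abs(calls$start_bp[matched[hit]] - truth$start_bp[hit])
    de <- abs(calls$end_bp[matched[hit]] - truth$end_bp[hit])
    mean(ds <= bin & de <= bin)
  } else NA_real_
  list(truth = truth, calls = calls, matched = matched,
       sensitivity = mean(hit),
       false_calls_per_genome =
         (nrow(calls) - length(unique(matched[hit]))) / n_samples,
       boundary_within_1bin = b_ok,
       n_truth = nrow(truth), n_calls = nrow(calls))
}
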