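# Raw bin counts -> denoised diploid-ratio profiles.
#
# Order of operations per sample: drop empty/unusable bins, LOESS-detrend the
# counts against GC, scale to the retained-bin mean, subtract the projection
# onto the top principal components of a euploid control cohort, rescale so
# the masked-in mean is 1.0 (diploid expectation).

#' Retained-bin filter
#'
#' A bin is retained when it is usable (grid flag) and its observed count is
#' positive; empty and unusable bins are masked for all downstream steps.
#'
#' @param counts Counts tibble (one sample) aligned to `grid`.
#' @param grid Bin grid tibble.
#' @return Integer vector of retained bin indices (grid row numbers).
#' @export
filter_empty_bins <- function(counts, grid) {
  stopifnot_cols(counts, "count", "counts")
  stopifnot_cols(grid, "usable", "grid")
  if (nrow(counts) != nrow(grid))
    abort("`counts` and `grid` must have the same number of bins")
  keep <- which(grid$usable & counts$count > 0)
  if (length(keep) == 0)
    abort("sample unusable: every bin is empty or masked")
  keep
}

#' LOESS GC-bias correction
#'
#' Fits a local-linear LOESS of observed count on bin GC over the retained
#' bins and detrends:
#' `corrected_i = observed_i - (fitted_i - rc_global)`, where `rc_global` is
#' the mean observed count over retained bins. A perfectly mean-unbiased fit
#' leaves the retained-bin mean equal to `rc_global`.
#'
#' @param counts Counts tibble (one sample) aligned to `grid`.
#' @param grid Bin grid tibble with a `gc` column.
#' @param span LOESS span (fraction of points in each local window).
#' @param degree Local polynomial degree (1 = local-linear).
#' @param family `"symmetric"` (default) fits with Tukey-biweight
#'   iterations so bins carrying real copy-number shifts do not drag the
#'   GC trend at their GC values; `"gaussian"` is plain least squares.
#' @return A list with `corrected` (the counts tibble plus a `corrected`
#'   column, NA on masked bins) and `model` (a `correction_model`: span,
#'   `rc_global`, fitted values, retained indices).
#' @export
loess_gc_correct <- function(counts, grid, span = 0.3, degree = 1,
                             family = c("symmetric", "gaussian")) {
  family <- match.arg(family)
  keep <- filter_empty_bins(counts, grid)
  gc <- grid$gc[keep]
  obs <- counts$count[keep]
  if (length(keep) < 30)
    abort("too few retained bins for a GC fit (need >= 30)")
  if (length(unique(gc)) < 2)
    abort("degenerate GC: all retained bins share one GC value")
  fit <- tryCatch(
    suppressWarnings(loess(obs ~ gc, span = span, degree = degree,
                           family = family)),
    error = function(e) abort(paste0("LOESS GC fit failed: ",
                                     conditionMessage(e))))
  fitted <- as.numeric(predict(fit, newdata = data.frame(gc = gc)))
  if (any(!is.finite(fitted)))
    abort("LOESS GC fit produced non-finite predictions")
  rc_global <- mean(obs)
  corrected <- rep(NA_real_, nrow(grid))
  corrected[keep] <- obs - (fitted - rc_global)
  out <- counts
  out$corrected <- corrected
  model <- structure(
    list(loess_span = span, degree = degree, rc_global = rc_global,
         fitted = fitted, retained = keep),
    class = "correction_model")
  list(corrected = out, model = model)
}

#' @export
print.correction_model <- function(x, ...) {
  cat(sprintf(
    "<correction_model> LOESS span %.2f, degree %d; %d retained bins; rc_global %.2f\n",
    x$loess_span, x$degree, length(x$retained), x$rc_global))
  invisible(x)
}

#' @export
glance.correction_model <- function(x, ...) {
  tibble(loess_span = x$loess_span, degree = x$degree,
         rc_global = x$rc_global, n_retained = length(x$retained))
}

#' @export
tidy.correction_model <- function(x, ...) {
  tibble(bin = x$retained, fitted = x$fitted)
}

# long counts tibble (sample_id x bin) -> samples-by-bins matrix in grid order
cohort_matrix <- function(counts) {
  stopifnot_cols(counts, c("sample_id", "count"), "counts")
  parts <- split(counts$count,
                 factor(counts$sample_id, levels = unique(counts$sample_id)))
  if (length(unique(lengths(parts))) != 1)
    abort("samples have differing bin counts")
  do.call(rbind, parts)
}

#' Low-coverage bin mask from a control cohort
#'
#' Bins whose mean count across controls falls below `threshold_fraction`
#' times the global mean (over all bins) are masked out; these correspond to
#' low-complexity genomic regions with insufficient unique-read coverage.
#'
#' @param controls Long counts tibble (>= 2 samples) or a samples-by-bins
#'   numeric matrix.
#' @param threshold_fraction Fraction of the global mean below which a bin is
#'   masked (default 0.1).
#' @return Logical vector, TRUE = sufficiently covered.
#' @export
mask_low_coverage_bins <- function(controls, threshold_fraction = 0.1) {
  m <- if (is.matrix(controls)) controls else cohort_matrix(controls)
  if (nrow(m) < 2) abort("need at least 2 control samples")
  bin_means <- colMeans(m)
  bin_means >= threshold_fraction * mean(bin_means)
}

#' Fit a PCA denoising reference from euploid controls
#'
#' Each control is GC-corrected, scaled to its retained-bin mean, and the top
#' `n_components` principal directions of the centred control matrix (over
#' masked-in bins) are extracted. Projections onto these directions capture
#' shared higher-order artifacts; [pca_normalize()] removes them from test
#' samples.
#'
#' @param controls Long counts tibble of control samples (no CNVs expected).
#' @param grid Bin grid tibble.
#' @param n_components Number of top components K (0 disables denoising;
#'   must be < number of controls).
#' @param loess_span Span for the per-control GC correction.
#' @param min_coverage_frac Passed to [mask_low_coverage_bins()].
#' @return A `pca_reference` object: `n_components`, `bin_mean` (full-length,
#'   NA off-mask), `rotation` (K x n-masked-bins, orthonormal rows), `mask`,
#'   `sdev` (component singular values / sqrt(n-1)), and the spans used.
#' @export
fit_pca_reference <- function(controls, grid, n_components = 5,
                              loess_span = 0.3, min_coverage_frac = 0.1) {
  m <- cohort_matrix(controls)
  n_ctrl <- nrow(m)
  if (n_components >= n_ctrl)
    abort("`n_components` must be smaller than the number of controls")
  if (ncol(m) != nrow(grid))
    abort("controls and grid have differing bin counts")
  cov_ok <- mask_low_coverage_bins(m, min_coverage_frac)
  mask <- grid$usable & cov_ok & apply(m > 0, 2, all)

  scaled <- matrix(NA_real_, nrow = n_ctrl, ncol = ncol(m))
  ids <- rownames(m)
  for (s in seq_len(n_ctrl)) {
    one <- tibble(sample_id = ids[s], count = m[s, ])
    cor_s <- loess_gc_correct(one, grid, span = loess_span)$corrected$corrected
    scaled[s, ] <- cor_s / mean(cor_s[mask], na.rm = TRUE)
  }
  x <- scaled[, mask, drop = FALSE]
  bin_mean_m <- colMeans(x)
  centred <- sweep(x, 2, bin_mean_m)
  if (n_components > 0) {
    sv <- svd(centred, nu = 0, nv = n_components)
    rotation <- t(sv$v)
    sdev <- sv$d[seq_len(n_components)] / sqrt(max(1, n_ctrl - 1))
  } else {
    rotation <- matrix(0, nrow = 0, ncol = sum(mask))
    sdev <- numeric()
  }
  bin_mean <- rep(NA_real_, nrow(grid))
  bin_mean[mask] <- bin_mean_m
  structure(
    list(n_components = n_components, bin_mean = bin_mean,
         rotation = rotation, mask = mask, sdev = sdev,
         loess_span = loess_span, min_coverage_frac = min_coverage_frac,
         n_controls = n_ctrl),
    class = "pca_reference")
}

#' @export
print.pca_reference <- function(x, ...) {
  cat(sprintf(
    "<pca_reference> K = %d components from %d controls over %d masked-in bins\n",
    x$n_components, x$n_controls, sum(x$mask)))
  invisible(x)
}

#' @export
glance.pca_reference <- function(x, ...) {
  tibble(n_components = x$n_components, n_controls = x$n_controls,
         n_bins = sum(x$mask),
         var_explained = sum(x$sdev^2))
}

#' @export
tidy.pca_reference <- function(x, ...) {
  tibble(component = seq_along(x$sdev), sdev = x$sdev)
}

#' PCA artifact removal and diploid-ratio scaling
#'
#' Scales a GC-corrected sample to its masked-in mean, subtracts its
#' projection onto the control-derived top components, re-adds the control
#' bin means, and rescales so the masked-in mean ratio is exactly 1 (diploid
#' expectation). Projection coefficients are fitted by least squares on bins
#' surviving one round of outlier trimming (|z| > `trim_z`) so genuine CNV
#' signal is not soaked up by the denoising.
#'
#' @param corrected Output of [loess_gc_correct()] (the list or its
#'   `corrected` tibble) for one sample.
#' @param reference A [fit_pca_reference()] object (`n_components = 0` makes
#'   this an identity apart from mean scaling).
#' @param grid Bin grid tibble.
#' @param trim_z Outlier threshold for projection fitting.
#' @return A normalized-profile tibble: `sample_id`, `chrom`, `start`, `end`,
#'   `ratio` (NA off-mask), `mask`.
#' @export
pca_normalize <- function(corrected, reference, grid, trim_z = 3) {
  if (is.list(corrected) && !is.data.frame(corrected))
    corrected <- corrected$corrected
  stopifnot_cols(corrected, "corrected", "corrected")
  stopifnot(inherits(reference, "pca_reference"))
  if (nrow(corrected) != length(reference$mask))
    abort("sample and reference have differing bin counts")
  mask <- reference$mask & is.finite(corrected$corrected)
  ref_sel <- which(reference$mask)          # columns of `rotation`
  sel <- match(which(mask), ref_sel)        # sample mask within reference mask
  s <- corrected$corrected[mask] / mean(corrected$corrected[mask])
  d <- s - reference$bin_mean[mask]
  if (reference$n_components > 0) {
    v <- t(reference$rotation[, sel, drop = FALSE])  # bins x K
    z <- (d - mean(d)) / max(sd(d), .Machine$double.eps)
    keep <- abs(z) <= trim_z
    beta <- tryCatch(
      solve(crossprod(v[keep, , drop = FALSE]),
            crossprod(v[keep, , drop = FALSE], d[keep])),
      error = function(e) abort("PCA projection is singular on this sample"))
    d <- d - as.numeric(v %*% beta)
  }
  r <- d + reference$bin_mean[mask]
  ratio <- rep(NA_real_, nrow(corrected))
  ratio[mask] <- r / mean(r)
  out <- grid
  out$sample_id <- if ("sample_id" %in% names(corrected))
    corrected$sample_id[1] else "S1"
  out$ratio <- ratio
  out$mask <- mask
  select(out, "sample_id", "chrom", "start", "end", "ratio", "mask")
}

#' Full per-sample normalization
#'
#' Convenience wrapper: retained-bin filtering, LOESS GC correction, PCA
#' artifact removal, low-coverage masking — raw counts in, diploid-ratio
#' profile out.
#'
#' @param counts Counts tibble for one sample.
#' @param grid Bin grid tibble.
#' @param reference A [fit_pca_reference()] object.
#' @param trim_z Outlier threshold for projection fitting.
#' @return Normalized-profile tibble (see [pca_normalize()]).
#' @examples
#' \donttest{
#' spec <- simulation_spec(n_chromosomes = 2, chromosome_length_bp = 5e6,
#'                         artifact_rank = 0, dropout_fraction = 0)
#' grid <- simulate_bin_grid(spec)
#' cohort <- simulate_cohort(grid, spec, n_samples = 8, seed = 7)
#' ref <- fit_pca_reference(cohort$counts, grid, n_components = 2)
#' sample1 <- dplyr::filter(cohort$counts, sample_id == "S0001")
#' prof <- normalize_profile(sample1, grid, ref)
#' mean(prof$ratio[prof$mask])  # ~1: diploid expectation
#' }
#' @export
normalize_profile <- function(counts, grid, reference, trim_z = 3) {
  cor <- loess_gc_correct(counts, grid, span = reference$loess_span)
  pca_normalize(cor$corrected, reference, grid, trim_z = trim_z)
}
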