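# Circular binary segmentation of normalized ratio profiles.

#' CBS parameters
#'
#' @param alpha Significance level for accepting a split (permutation
#'   p-value must fall below it).
#' @param n_permutations Permutations per split test; the p-value uses the
#'   +1 correction, p = (b + 1) / (B + 1).
#' @param min_seg_bins Minimum arc width (and minimum segment size) in bins.
#' @param prune_mean_diff Adjacent segments whose means differ by less than
#'   this (ratio units) are merged in a final pruning pass. The default 0.1
#'   sits above the within-event amplitude structure that additive GC
#'   detrending leaves behind (about half the regional bias spread) and far
#'   below the 0.3 deviation that separates diploid from called segments, so
#'   single-copy events are not fragmented while real transitions survive.
#' @param seed Integer seed; every permutation stream is derived from it (and
#'   from the stretch being tested), so segmentation is reproducible and
#'   per-stretch decisions do not depend on evaluation order.
#' @return A list of class `cbs_params`.
#' @export
cbs_params <- function(alpha = 0.01, n_permutations = 10000L,
                       min_seg_bins = 2L, prune_mean_diff = 0.1,
                       seed = 1L) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1)")
  if (n_permutations < 1) abort("`n_permutations` must be >= 1")
  if (min_seg_bins < 1) abort("`min_seg_bins` must be >= 1")
  structure(list(alpha = alpha, n_permutations = as.integer(n_permutations),
                 min_seg_bins = as.integer(min_seg_bins),
                 prune_mean_diff = prune_mean_diff, seed = as.integer(seed)),
            class = "cbs_params")
}

#' Maximal circular-arc t statistic
#'
#' Over all circular arcs `(i, j]` (0-based half-open) of width between
#' `min_width` and `length(values) - min_width`, finds the arc maximizing
#' |t|, where t compares the arc mean against the complement mean with
#' pooled variance. Ties (equal t-squared within a relative 1e-10, e.g. the
#' two complementary arcs of one split) are broken by smallest `i`, then
#' smallest `j`.
#' Wrap-around arcs are complements of linear arcs and carry the same |t|,
#' so the scan over linear arcs covers the circle. A constant vector gives
#' t = 0 with a trivial arc.
#'
#' @param values Numeric vector, length >= 4, no NAs.
#' @param min_width Minimum arc (and complement) width.
#' @return A list with `i`, `j` (0-based half-open arc bounds) and `t_stat`
#'   (signed: arc mean minus complement mean).
#' @examples
#' max_arc_t(c(0, 0, 0, 0, 1, 1, 1, 1))
#' @export
max_arc_t <- function(values, min_width = 2) {
  if (length(values) < 4) abort("`values` must have length >= 4")
  if (any(!is.finite(values))) abort("`values` must be finite")
  if (min_width < 1 || 2 * min_width > length(values))
    abort("`min_width` out of range for this vector")
  res <- .cbs_scan_cpp(as.numeric(values), as.integer(min_width))
  list(i = res$i, j = res$j, t_stat = res$t)
}

# permutation split test for one stretch; deterministic given params$seed and
# the stretch identity (chromosome index, absolute lo/hi of the stretch)
cbs_split_test <- function(x, params, chrom_idx, lo, hi) {
  with_seed(derive_seed(params$seed, chrom_idx, lo, hi), {
    .cbs_perm_cpp(as.numeric(x), params$min_seg_bins,
                  params$n_permutations, params$alpha, TRUE)
  })
}

# recursive segmentation of one chromosome's masked-in ratio vector;
# returns integer breakpoints (positions after which a new segment starts,
# half-open indices into x)
segment_vector <- function(x, params, chrom_idx, offset = 0L) {
  n <- length(x)
  if (n < max(4L, 2L * params$min_seg_bins)) return(integer())
  res <- cbs_split_test(x, params, chrom_idx, offset, offset + n)
  if (res$t == 0 || res$p >= params$alpha) return(integer())
  i <- res$i
  j <- res$j
  cuts <- setdiff(unique(c(i, j)), c(0L, n))  # map arc to linear breakpoints
  if (length(cuts) == 0) return(integer())
  bounds <- c(0L, sort(cuts), n)
  out <- integer()
  for (p in seq_len(length(bounds) - 1)) {
    lo <- bounds[p]
    hi <- bounds[p + 1]
    sub <- segment_vector(x[(lo + 1):hi], params, chrom_idx, offset + lo)
    out <- c(out, lo + sub)
  }
  sort(unique(c(out, cuts)))
}

# merge adjacent segments whose means differ by < threshold (closest first)
prune_segments <- function(bounds, x, threshold) {
  repeat {
    k <- length(bounds) - 1  # number of segments
    if (k < 2) break
    means <- vapply(seq_len(k), function(s)
      mean(x[(bounds[s] + 1):bounds[s + 1]]), numeric(1))
    diffs <- abs(diff(means))
    w <- which.min(diffs)
    if (diffs[w] >= threshold) break
    bounds <- bounds[-(w + 1)]
  }
  bounds
}

#' Circular binary segmentation of a normalized profile
#'
#' Recursively splits each chromosome's masked-in ratio sequence where the
#' permutation p-value of the maximal arc |t| falls below `alpha`, then
#' merges adjacent segments with negligible mean difference. Masked bins are
#' excluded from the statistics, but a segment's genomic span bridges masked
#' gaps in its interior.
#'
#' @param profile Normalized-profile tibble (`chrom`, `start`, `end`,
#'   `ratio`, optional `mask`; bins with NA ratio are treated as masked).
#' @param params A [cbs_params()] object.
#' @return A tibble of segments: `sample_id` (if present), `chrom`,
#'   `start_bin`, `end_bin` (0-based half-open indices into that
#'   chromosome's masked-in bin sequence), `start_bp`, `end_bp`, `n_bins`,
#'   `mean_ratio`. Segments partition the masked-in bins of each chromosome.
#' @examples
#' prof <- tibble::tibble(chrom = "chr1", start = 0:199 * 20000,
#'                        end = 1:200 * 20000,
#'                        ratio = rep(c(1, 1.5), each = 100))
#' cbs_segment(prof, cbs_params(n_permutations = 500, seed = 42))
#' @export
cbs_segment <- function(profile, params = cbs_params()) {
  stopifnot_cols(profile, c("chrom", "start", "end", "ratio"), "profile")
  stopifnot(inherits(params, "cbs_params"))
  mask <- if ("mask" %in% names(profile)) profile$mask else
    rep(TRUE, nrow(profile))
  mask <- mask & is.finite(profile$ratio)
  sid <- if ("sample_id" %in% names(profile)) profile$sample_id[1] else NULL
  chroms <- chrom_order(profile$chrom)
  segs <- purrr::map(seq_along(chroms), function(ci) {
    rows <- which(profile$chrom == chroms[ci] & mask)
    if (length(rows) == 0) return(NULL)
    x <- profile$ratio[rows]
    n <- length(x)
    cuts <- segment_vector(x, params, ci)
    bounds <- prune_segments(c(0L, cuts, n), x, params$prune_mean_diff)
    k <- length(bounds) - 1
    tibble(
      chrom = chroms[ci],
      start_bin = bounds[-length(bounds)],
      end_bin = bounds[-1],
      start_bp = profile$start[rows[bounds[-length(bounds)] + 1]],
      end_bp = profile$end[rows[bounds[-1]]],
      n_bins = diff(bounds),
      mean_ratio = vapply(seq_len(k), function(s)
        mean(x[(bounds[s] + 1):bounds[s + 1]]), numeric(1))
    )
  })
  out <- bind_rows(purrr::compact(segs))
  if (!is.null(sid) && nrow(out) > 0)
    out <- mutate(out, sample_id = sid, .before = 1)
  out
}
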