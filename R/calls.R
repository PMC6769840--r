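# Segments -> maternal CNV calls.

#' Call maternal CNVs from segments
#'
#' A segment becomes a gain call when its mean diploid ratio reaches at least
#' `1 + min_fraction * 0.5` (default 1.3) and a loss call when it falls to at
#' most `1 - min_fraction * 0.5` (default 0.7), provided its genomic span is
#' at least `min_length_kbp` (default 600 kbp). Both thresholds are
#' inclusive. The 0.5 factor is the expected diploid-ratio shift of a full
#' heterozygous single-copy event; `min_fraction = 0.6` therefore requires at
#' least 60% of a single-copy shift, tolerating dilution and noise.
#'
#' Call coordinates are the segment coordinates (no resizing); a segment's
#' span bridges masked bins in its interior, so length is genomic.
#'
#' @param segments Segment tibble from [cbs_segment()].
#' @param min_length_kbp Minimum genomic span in kbp (inclusive).
#' @param min_fraction Minimum fraction of a single-copy shift (inclusive).
#' @return A tibble of calls: `sample_id` (if present), `chrom`, `start_bp`,
#'   `end_bp`, `type` ("gain"/"loss"), `mean_ratio`, `n_bins` (if present),
#'   `length_bp`, `length_kbp`.
#' @examples
#' segs <- tibble::tibble(chrom = "chr1", start_bp = 0, end_bp = 6e5,
#'                        mean_ratio = c(1.3))
#' call_cnvs(segs)
#' @export
call_cnvs <- function(segments, min_length_kbp = 600, min_fraction = 0.6) {
  stopifnot_cols(segments, c("chrom", "start_bp", "end_bp", "mean_ratio"),
                 "segments")
  gain_thr <- 1 + min_fraction * 0.5
  loss_thr <- 1 - min_fraction * 0.5
  tol <- 1e-9  # keep literal boundary values (e.g. ratio exactly 1.3) inclusive
  out <- segments |>
    mutate(length_bp = .data$end_bp - .data$start_bp,
           type = dplyr::case_when(
             .data$mean_ratio >= gain_thr - tol ~ "gain",
             .data$mean_ratio <= loss_thr + tol ~ "loss",
             TRUE ~ NA_character_)) |>
    filter(!is.na(.data$type),
           .data$length_bp >= min_length_kbp * 1000) |>
    mutate(length_kbp = .data$length_bp / 1000)
  keep <- intersect(c("sample_id", "chrom", "start_bp", "end_bp", "type",
                      "mean_ratio", "n_bins", "length_bp", "length_kbp"),
                    names(out))
  out[keep]
}

#' End-to-end calling for one sample
#'
#' Normalizes, segments and calls a single sample's raw bin counts.
#'
#' @param counts Counts tibble for one sample.
#' @param grid Bin grid tibble.
#' @param reference A [fit_pca_reference()] object.
#' @param params A [cbs_params()] object.
#' @param min_length_kbp,min_fraction Calling thresholds, see [call_cnvs()].
#' @return A CNV call tibble.
#' @export
call_sample <- function(counts, grid, reference, params = cbs_params(),
                        min_length_kbp = 600, min_fraction = 0.6) {
  profile <- normalize_profile(counts, grid, reference)
  segs <- cbs_segment(profile, params)
  call_cnvs(segs, min_length_kbp = min_length_kbp,
            min_fraction = min_fraction)
}
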