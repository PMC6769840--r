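# A fully synthetic cohort call set constructed so that its aggregate
# statistics equal the tallies reported for the 5018-women shallow-WGS NIPT
# reanalysis this pipeline models. The individual coordinates, sample
# assignments and database records are invented; only the aggregates
# (counts, medians, Mbp cells, overlap-class and carrier tallies) are
# meaningful. It exists so the summary, annotation and clustering modules
# can be exercised against known printed statistics.

#' Synthetic reference cohort call set
#'
#' Builds a synthetic set of 225 maternal CNV calls (178 gains, 47 losses)
#' across 212 carrier samples of a 5018-individual cohort, together with a
#' known-variant database and a gene interval set, constructed so that the
#' aggregate statistics computed by [summarize_cohort()],
#' [classify_overlap()], [coding_attribution()] and [cluster_variants()]
#' reproduce the published cohort report this pipeline models:
#' 79.11%/20.89% gains/losses, sizes 600-7820 kbp with medians 820/830/800
#' kbp, overlap classes 137/66/22 (60.89%/29.33%/9.78%), 212 carriers
#' (4.2%, 95.28% with a single call), one recurrent duplication with 11
#' detection events on chr2, 207 gene-overlapping calls (92%), and the Mbp
#' table 191.54/3.27/188.27 (gain), 46.98/0.44/46.54 (loss),
#' 238.52/3.71/234.81 (total).
#'
#' Every coordinate is synthetic: calls are laid out disjointly along 22
#' autosomes (except the deliberately recurrent variant), so the clustering
#' and interval algebra act on well-defined ground truth.
#'
#' @return A list with `calls` (tibble), `db` (known-variant records),
#'   `genes` (gene intervals) and `cohort_size` (5018).
#' @examples
#' ref <- synthetic_reference_cohort()
#' nrow(ref$calls)
#' @export
synthetic_reference_cohort <- function() {
  cohort_size <- 5018L

  # gain lengths: median 830 kbp, total 191.54 Mbp, max 7820 kbp (n = 178)
  gain_len <- c(rep(700e3, 88), 830e3, 830e3, 920e3, rep(1390e3, 86), 7820e3)
  # loss lengths: median 800 kbp, total 46.98 Mbp, min 600 kbp (n = 47)
  loss_len <- c(600e3, rep(650e3, 22), 800e3, 820e3, rep(1385e3, 21), 1375e3)

  # one recurrent 700 kbp duplication on chr2 seen in 11 samples; all other
  # variants are singletons placed disjointly (>= 1 Mbp apart)
  n_recur <- 11L
  recur <- tibble(chrom = "chr2", start_bp = 36.6e6, end_bp = 37.3e6,
                  type = "gain", length = 700e3)

  singles_len <- c(gain_len[-seq_len(n_recur)], loss_len)  # 167 + 47 = 214
  singles_type <- c(rep("gain", length(gain_len) - n_recur),
                    rep("loss", length(loss_len)))
  chroms <- sprintf("chr%d", 1:22)
  offset <- setNames(rep(1e6, 22), chroms)
  offset["chr2"] <- 40e6  # keep clear of the recurrent variant
  sing <- vector("list", length(singles_len))
  for (v in seq_along(singles_len)) {
    ch <- chroms[(v - 1) %% 22 + 1]
    sing[[v]] <- tibble(chrom = ch, start_bp = offset[ch],
                        end_bp = offset[ch] + singles_len[v],
                        type = singles_type[v], length = singles_len[v])
    offset[ch] <- offset[ch] + singles_len[v] + 1e6
  }
  variants <- bind_rows(recur[rep(1, n_recur), ], bind_rows(sing))

  # carriers: 202 samples with one call, 9 with two, 1 with five (225 calls
  # in 212 individuals; the recurrent variant sits in 11 distinct samples)
  sample_ids <- c(sprintf("S%04d", 1:202),
                  rep(sprintf("S%04d", 203:211), each = 2),
                  rep("S0212", 5))
  calls <- variants |>
    mutate(sample_id = sample_ids,
           mean_ratio = if_else(.data$type == "gain", 1.5, 0.5),
           length_bp = .data$length,
           length_kbp = .data$length / 1000) |>
    select("sample_id", "chrom", "start_bp", "end_bp", "type", "mean_ratio",
           "length_bp", "length_kbp")

  # overlap classes, assigned per variant (identical calls share records):
  # full 137 (11 recurrent gains + 99 gains + 27 losses), partial 66
  # (51 gains + 15 losses), none 22 (17 gains + 5 losses)
  uniq <- calls |>
    mutate(row = row_number()) |>
    group_by(.data$chrom, .data$start_bp, .data$end_bp, .data$type) |>
    summarise(rows = list(.data$row), .groups = "drop")
  gain_u <- which(uniq$type == "gain")   # 168 unique gain variants
  loss_u <- which(uniq$type == "loss")   # 47 unique loss variants
  class_u <- character(nrow(uniq))
  recur_u <- which(purrr::map_int(uniq$rows, length) == n_recur)
  gain_rest <- setdiff(gain_u, recur_u)
  class_u[recur_u] <- "full"
  class_u[gain_rest[1:99]] <- "full"
  class_u[gain_rest[100:150]] <- "partial"
  class_u[gain_rest[151:167]] <- "none"
  class_u[loss_u[1:27]] <- "full"
  class_u[loss_u[28:42]] <- "partial"
  class_u[loss_u[43:47]] <- "none"
  db <- purrr::map(which(class_u != "none"), function(v) {
    len <- uniq$end_bp[v] - uniq$start_bp[v]
    end <- if (class_u[v] == "full") uniq$end_bp[v] else
      uniq$start_bp[v] + floor(len / 2)
    tibble(chrom = uniq$chrom[v], start_bp = uniq$start_bp[v], end_bp = end,
           type = uniq$type[v], id = sprintf("var%03d", v),
           label = if (class_u[v] == "full") "known" else "known-partial")
  }) |> bind_rows()

  # genes: 207 gene-overlapping calls (167 gains incl. all 11 recurrent, 40
  # losses); coding bp totals 3.27 Mbp (gain) and 0.44 Mbp (loss). The
  # largest gain carries 3,104,000 coding bp, one large loss 401,000; every
  # other gene-overlapping variant a 1000 bp gene.
  gain_sorted <- gain_rest[order(uniq$end_bp[gain_rest] -
                                   uniq$start_bp[gain_rest])]
  big_gain <- gain_sorted[length(gain_sorted)]        # the 7820 kbp gain
  small_gains <- setdiff(gain_rest, big_gain)
  loss_sorted <- loss_u[order(uniq$end_bp[loss_u] - uniq$start_bp[loss_u])]
  big_loss <- loss_sorted[length(loss_sorted) - 1]    # a 1385 kbp loss
  small_losses <- setdiff(loss_u, big_loss)
  gene_small <- c(recur_u, small_gains[1:155], small_losses[1:39])
  coding_of <- setNames(rep(1000, length(gene_small)), gene_small)
  coding_of[as.character(big_gain)] <- 3104000
  coding_of[as.character(big_loss)] <- 401000
  genes <- purrr::map(names(coding_of), function(v) {
    vi <- as.integer(v)
    tibble(chrom = uniq$chrom[vi], start = uniq$start_bp[vi] + 1000,
           end = uniq$start_bp[vi] + 1000 + coding_of[v],
           name = sprintf("GENE%03d", vi))
  }) |> bind_rows()

  list(calls = calls, db = db, genes = genes, cohort_size = cohort_size)
}
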