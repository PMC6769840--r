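# Population-level aggregation of CNV calls: reciprocal-overlap clustering
# into recurrent variants, per-variant carrier frequencies, counts and
# percentages by type, size statistics, per-chromosome distribution, and the
# coding/non-coding Mbp table.

#' Cluster calls into recurrent variants by reciprocal overlap
#'
#' Two same-type calls belong to the same variant when their reciprocal
#' overlap (intersection length as a fraction of each call's length) reaches
#' `reciprocal_overlap`; clusters are the single-linkage closure of this
#' relation. Per-variant frequency is the number of distinct carrier samples
#' divided by the cohort size.
#'
#' @param calls CNV call tibble across the cohort (`sample_id`, `chrom`,
#'   `start_bp`, `end_bp`, `type`).
#' @param cohort_size Number of individuals screened (not just carriers).
#' @param reciprocal_overlap Minimum reciprocal-overlap fraction (default
#'   0.5, the field's usual convention for declaring two calls the same
#'   variant).
#' @return A tibble of clusters: `cluster_id`, `chrom`, `start_bp`,
#'   `end_bp` (median member endpoints), `type`, `n_events` (member calls),
#'   `n_carriers` (distinct samples), `frequency`, `members` (list column of
#'   sample ids). `sum(n_events)` equals `nrow(calls)`.
#' @examples
#' calls <- tibble::tibble(sample_id = c("a", "b"), chrom = "chr2",
#'                         start_bp = 0, end_bp = 1e6, type = "gain")
#' cluster_variants(calls, cohort_size = 100)
#' @export
cluster_variants <- function(calls, cohort_size, reciprocal_overlap = 0.5) {
  stopifnot_cols(calls, c("sample_id", "chrom", "start_bp", "end_bp",
                          "type"), "calls")
  if (reciprocal_overlap <= 0 || reciprocal_overlap > 1)
    abort("`reciprocal_overlap` must be in (0, 1]")
  n <- nrow(calls)
  if (cohort_size < n_distinct(calls$sample_id))
    abort("`cohort_size` is smaller than the number of carrier samples")
  if (n == 0) {
    return(tibble(cluster_id = integer(), chrom = character(),
                  start_bp = numeric(), end_bp = numeric(),
                  type = character(), n_events = integer(),
                  n_carriers = integer(), frequency = numeric(),
                  members = list()))
  }

  # union-find over call indices
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  unite <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[rb] <<- ra
  }

  gr <- as_granges0(calls)
  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                      drop.redundant = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  if (length(qh) > 0) {
    same_type <- calls$type[qh] == calls$type[sh]
    w <- pmax(0, pmin(calls$end_bp[qh], calls$end_bp[sh]) -
                pmax(calls$start_bp[qh], calls$start_bp[sh]))
    len_q <- calls$end_bp[qh] - calls$start_bp[qh]
    len_s <- calls$end_bp[sh] - calls$start_bp[sh]
    ok <- same_type & (w / len_q >= reciprocal_overlap) &
      (w / len_s >= reciprocal_overlap)
    for (e in which(ok)) unite(qh[e], sh[e])
  }
  root <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), root)

  out <- purrr::map(groups, function(idx) {
    tibble(
      chrom = calls$chrom[idx[1]],
      start_bp = round(median(calls$start_bp[idx])),
      end_bp = round(median(calls$end_bp[idx])),
      type = calls$type[idx[1]],
      n_events = length(idx),
      n_carriers = n_distinct(calls$sample_id[idx]),
      members = list(sort(unique(calls$sample_id[idx])))
    )
  })
  bind_rows(out) |>
    arrange(dplyr::desc(.data$n_events), .data$chrom, .data$start_bp) |>
    mutate(cluster_id = row_number(),
           frequency = .data$n_carriers / cohort_size,
           .before = 1) |>
    select("cluster_id", "chrom", "start_bp", "end_bp", "type", "n_events",
           "n_carriers", "frequency", "members")
}

#' Attach cytoband labels to intervals
#'
#' Labels each interval with the chromosome band containing its midpoint
#' (e.g. "2p22"), the conventional way CNV locations are reported. Without
#' a band table, callers simply keep coordinates.
#'
#' @param intervals Tibble with `chrom` and `start_bp`/`end_bp` (or
#'   `start`/`end`) columns, e.g. [cluster_variants()] output.
#' @param cytobands Band table: `chrom`, `start`, `end`, `name` (band name
#'   without the chromosome prefix, e.g. "p22"), as read by [read_bed()]
#'   from a UCSC-style cytoband file.
#' @return `intervals` with a `cytoband` column ("2p22"-style; NA when no
#'   band covers the midpoint).
#' @export
label_cytobands <- function(intervals, cytobands) {
  sc <- if ("start_bp" %in% names(intervals)) "start_bp" else "start"
  ec <- if ("end_bp" %in% names(intervals)) "end_bp" else "end"
  stopifnot_cols(intervals, c("chrom", sc, ec), "intervals")
  stopifnot_cols(cytobands, c("chrom", "start", "end", "name"), "cytobands")
  mid <- (intervals[[sc]] + intervals[[ec]]) / 2
  label <- rep(NA_character_, nrow(intervals))
  for (r in seq_len(nrow(intervals))) {
    hit <- which(cytobands$chrom == intervals$chrom[r] &
                   cytobands$start <= mid[r] & mid[r] < cytobands$end)
    if (length(hit) > 0)
      label[r] <- paste0(sub("^chr", "", intervals$chrom[r]),
                         cytobands$name[hit[1]])
  }
  mutate(intervals, cytoband = label)
}

#' Coding/non-coding Mbp table by variant type
#'
#' One row per type plus a total row; columns are call count, total Mbp,
#' coding Mbp and non-coding Mbp, each to 2 decimals. Requires `coding_bp`
#' from [coding_attribution()].
#'
#' @param calls Attributed CNV call tibble.
#' @return A tibble with rows "gain", "loss", "total".
#' @export
mbp_table <- function(calls) {
  template <- tibble(type = c("gain", "loss"), n = 0L, total_mbp = 0,
                     coding_mbp = 0, noncoding_mbp = 0)
  if (nrow(calls) > 0) {
    stopifnot_cols(calls, c("type", "start_bp", "end_bp", "coding_bp"),
                   "calls")
    got <- calls |>
      mutate(length_bp = .data$end_bp - .data$start_bp) |>
      group_by(.data$type) |>
      summarise(n = n(),
                total_mbp = round_half_up(sum(.data$length_bp) / 1e6, 2),
                coding_mbp = round_half_up(sum(.data$coding_bp) / 1e6, 2),
                noncoding_mbp = round_half_up(
                  sum(.data$length_bp - .data$coding_bp) / 1e6, 2))
    template <- bind_rows(got,
                          filter(template, !.data$type %in% got$type)) |>
      arrange(.data$type)
  }
  total <- summarise(template,
                     type = "total", n = sum(.data$n),
                     total_mbp = round_half_up(sum(.data$total_mbp), 2),
                     coding_mbp = round_half_up(sum(.data$coding_mbp), 2),
                     noncoding_mbp = round_half_up(sum(.data$noncoding_mbp), 2))
  bind_rows(template, total)
}

#' Cohort-level CNV summary
#'
#' Aggregates calls into the population summary: counts and percentages by
#' type (2 decimals), size statistics in kbp, per-chromosome counts, carrier
#' statistics (carrier percentage to 1 decimal, as conventionally printed),
#' overlap-class tabulation (when `overlap_class` is present), the
#' coding/non-coding Mbp table (when `coding_bp` is present), and
#' per-variant frequencies (4 decimals) from [cluster_variants()].
#'
#' @param calls CNV call tibble, optionally annotated.
#' @param cohort_size Number of individuals screened.
#' @param clusters Optional precomputed [cluster_variants()] output.
#' @param reciprocal_overlap Clustering threshold when `clusters` is NULL.
#' @return An object of class `cohort_summary`; see [glance.cohort_summary()]
#'   and [tidy.cohort_summary()].
#' @export
summarize_cohort <- function(calls, cohort_size, clusters = NULL,
                             reciprocal_overlap = 0.5) {
  if (nrow(calls) > 0)
    stopifnot_cols(calls, c("sample_id", "chrom", "start_bp", "end_bp",
                            "type"), "calls")
  else
    calls <- tibble(sample_id = character(), chrom = character(),
                    start_bp = numeric(), end_bp = numeric(),
                    type = character())
  calls <- mutate(calls, length_bp = .data$end_bp - .data$start_bp,
                  length_kbp = (.data$end_bp - .data$start_bp) / 1000)
  n_calls <- nrow(calls)
  n_gain <- sum(calls$type == "gain")
  n_loss <- sum(calls$type == "loss")
  pct <- function(num, den, digits = 2)
    if (den > 0) round_half_up(100 * num / den, digits) else 0

  sizes <- list(
    median_kbp = if (n_calls) median(calls$length_kbp) else 0,
    median_gain_kbp = if (n_gain) median(calls$length_kbp[calls$type ==
                                                            "gain"]) else 0,
    median_loss_kbp = if (n_loss) median(calls$length_kbp[calls$type ==
                                                            "loss"]) else 0,
    min_kbp = if (n_calls) min(calls$length_kbp) else 0,
    max_kbp = if (n_calls) max(calls$length_kbp) else 0)

  per_chrom <- if (n_calls) {
    count(calls, .data$chrom, .data$type) |>
      tidyr::pivot_wider(names_from = "type", values_from = "n",
                         values_fill = 0L) |>
      mutate(chrom = factor(.data$chrom, levels = chrom_order(.data$chrom))) |>
      arrange(.data$chrom)
  } else tibble(chrom = factor(character()))

  n_carriers <- n_distinct(calls$sample_id)
  per_sample <- if (n_calls) count(calls, .data$sample_id) else
    tibble(sample_id = character(), n = integer())
  n_single <- sum(per_sample$n == 1)

  overlap <- NULL
  if ("overlap_class" %in% names(calls) && n_calls > 0) {
    overlap <- tibble(class = c("full", "partial", "none")) |>
      left_join(count(calls, class = .data$overlap_class), by = "class") |>
      mutate(n = dplyr::coalesce(.data$n, 0L),
             pct = pct(.data$n, n_calls))
  }

  mbp <- NULL
  coding <- NULL
  if ("coding_bp" %in% names(calls) && n_calls > 0) {
    mbp <- mbp_table(calls)
    gain_row <- filter(mbp, .data$type == "gain")
    loss_row <- filter(mbp, .data$type == "loss")
    tot_row <- filter(mbp, .data$type == "total")
    frac <- function(cod, tot)
      if (tot > 0) round_half_up(100 * cod / tot, 2) else 0
    coding <- list(
      n_gene_overlapping = sum(calls$coding_bp > 0),
      pct_gene_overlapping = pct(sum(calls$coding_bp > 0), n_calls),
      pct_coding_overall = frac(tot_row$coding_mbp, tot_row$total_mbp),
      pct_coding_gain = frac(gain_row$coding_mbp, gain_row$total_mbp),
      pct_coding_loss = frac(loss_row$coding_mbp, loss_row$total_mbp))
  }

  if (is.null(clusters) && n_calls > 0)
    clusters <- cluster_variants(calls, cohort_size,
                                 reciprocal_overlap = reciprocal_overlap)
  if (!is.null(clusters) && nrow(clusters) > 0)
    clusters <- mutate(clusters, frequency = round(.data$frequency, 4))

  structure(list(
    cohort_size = cohort_size,
    n_calls = n_calls, n_gain = n_gain, n_loss = n_loss,
    pct_gain = pct(n_gain, n_calls), pct_loss = pct(n_loss, n_calls),
    gain_loss_ratio = if (n_loss > 0) round_half_up(n_gain / n_loss, 1)
      else NA_real_,
    sizes = sizes, per_chrom = per_chrom,
    n_carriers = n_carriers,
    pct_carriers = pct(n_carriers, cohort_size, digits = 1),
    n_single_call = n_single,
    pct_single_call = pct(n_single, n_carriers),
    pct_multi_call = pct(n_carriers - n_single, n_carriers),
    overlap = overlap, mbp = mbp, coding = coding,
    clusters = clusters,
    max_cluster_frequency = if (!is.null(clusters) && nrow(clusters) > 0)
      max(clusters$frequency) else 0,
    calls = calls
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d CNV calls in %d of %d individuals (%.1f%%)\n",
              x$n_calls, x$n_carriers, x$cohort_size, x$pct_carriers))
  cat(sprintf("  gains: %d (%.2f%%)  losses: %d (%.2f%%)  ratio %.1f\n",
              x$n_gain, x$pct_gain, x$n_loss, x$pct_loss,
              x$gain_loss_ratio))
  cat(sprintf("  size (kbp): median %.0f [%.0f-%.0f]; gain %.0f, loss %.0f\n",
              x$sizes$median_kbp, x$sizes$min_kbp, x$sizes$max_kbp,
              x$sizes$median_gain_kbp, x$sizes$median_loss_kbp))
  if (!is.null(x$overlap)) {
    o <- x$overlap
    cat(sprintf("  overlap: full %d (%.2f%%), partial %d (%.2f%%), none %d (%.2f%%)\n",
                o$n[1], o$pct[1], o$n[2], o$pct[2], o$n[3], o$pct[3]))
  }
  if (!is.null(x$mbp)) {
    cat("  Mbp by type (n / total / coding / non-coding):\n")
    for (r in seq_len(nrow(x$mbp)))
      cat(sprintf("    %-5s %4d  %8.2f %6.2f %8.2f\n", x$mbp$type[r],
                  x$mbp$n[r], x$mbp$total_mbp[r], x$mbp$coding_mbp[r],
                  x$mbp$noncoding_mbp[r]))
    cat(sprintf("  coding fraction: %.2f%% overall (gain %.2f%%, loss %.2f%%); %d calls (%.2f%%) overlap genes\n",
                x$coding$pct_coding_overall, x$coding$pct_coding_gain,
                x$coding$pct_coding_loss, x$coding$n_gene_overlapping,
                x$coding$pct_gene_overlapping))
  }
  if (!is.null(x$clusters) && nrow(x$clusters) > 0)
    cat(sprintf("  %d distinct variants; max per-variant frequency %.4f\n",
                nrow(x$clusters), x$max_cluster_frequency))
  invisible(x)
}

#' One-row summary of a cohort summary
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @export
glance.cohort_summary <- function(x, ...) {
  tibble(
    cohort_size = x$cohort_size, n_calls = x$n_calls,
    n_gain = x$n_gain, n_loss = x$n_loss,
    pct_gain = x$pct_gain, pct_loss = x$pct_loss,
    gain_loss_ratio = x$gain_loss_ratio,
    median_kbp = x$sizes$median_kbp, min_kbp = x$sizes$min_kbp,
    max_kbp = x$sizes$max_kbp,
    n_carriers = x$n_carriers, pct_carriers = x$pct_carriers,
    pct_single_call = x$pct_single_call,
    n_variants = if (!is.null(x$clusters)) nrow(x$clusters) else NA_integer_,
    max_cluster_frequency = x$max_cluster_frequency,
    pct_coding_overall = if (!is.null(x$coding))
      x$coding$pct_coding_overall else NA_real_
  )
}

#' Long-format statistics of a cohort summary
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @export
tidy.cohort_summary <- function(x, ...) {
  g <- glance(x)
  tibble(statistic = names(g), value = as.numeric(g[1, ]))
}
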