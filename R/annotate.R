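# Overlap classification against known-variant records and coding/non-coding
# attribution. All interval algebra is delegated to GenomicRanges/IRanges;
# coordinates are 0-based half-open at the API boundary.

# records (db or genes) -> GRanges, tolerating either start/end or
# start_bp/end_bp column names
records_granges <- function(df) {
  sc <- if ("start_bp" %in% names(df)) "start_bp" else "start"
  ec <- if ("end_bp" %in% names(df)) "end_bp" else "end"
  stopifnot_cols(df, c("chrom", sc, ec), "intervals")
  if (any(df[[ec]] <= df[[sc]]))
    abort("intervals must satisfy end > start")
  as_granges0(df, sc, ec)
}

#' Classify calls by overlap with a known-variant database
#'
#' For each call, the type-compatible database records overlapping it are
#' collected and the call is classified as:
#' * `full` — the union of those records covers 100% of the call's bases
#'   (`mode = "union"`, the default), or a single record contains the call
#'   (`mode = "single_record"`), or some record has reciprocal overlap at
#'   least `reciprocal` (`mode = "reciprocal"`);
#' * `partial` — covered fraction in (0, 1);
#' * `none` — no overlap.
#' Classes are mutually exclusive and exhaustive over the call set.
#'
#' @param calls CNV call tibble.
#' @param db Database record tibble: `chrom`, `start_bp`/`start`,
#'   `end_bp`/`end`, optional `type` ("gain"/"loss"/"any") and `id`.
#' @param type_match Require record type to match call type (records typed
#'   "any" or untyped always match).
#' @param mode Definition of "full" overlap (see above).
#' @param reciprocal Reciprocal-overlap fraction for `mode = "reciprocal"`.
#' @return `calls` with `overlap_class` ("full"/"partial"/"none"),
#'   `overlap_fraction` (union-covered fraction of the call) and
#'   `overlap_ids` (comma-separated record ids, if `db` has `id`).
#' @export
classify_overlap <- function(calls, db, type_match = TRUE,
                             mode = c("union", "single_record", "reciprocal"),
                             reciprocal = 0.5) {
  mode <- match.arg(mode)
  stopifnot_cols(calls, c("chrom", "start_bp", "end_bp", "type"), "calls")
  n <- nrow(calls)
  res <- tibble(overlap_class = rep("none", n),
                overlap_fraction = rep(0, n),
                overlap_ids = rep(NA_character_, n))
  if (n == 0 || is.null(db) || nrow(db) == 0)
    return(dplyr::bind_cols(calls, res))

  gr_calls <- as_granges0(calls)
  gr_db <- records_granges(db)
  db_type <- if ("type" %in% names(db)) db$type else rep("any", nrow(db))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_calls, gr_db))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  if (type_match) {
    ok <- db_type[sh] == "any" | db_type[sh] == calls$type[qh]
    qh <- qh[ok]
    sh <- sh[ok]
  }
  db_start <- if ("start_bp" %in% names(db)) db$start_bp else db$start
  db_end <- if ("end_bp" %in% names(db)) db$end_bp else db$end
  for (ci in unique(qh)) {
    recs <- sh[qh == ci]
    call_len <- calls$end_bp[ci] - calls$start_bp[ci]
    inter <- GenomicRanges::intersect(gr_calls[ci],
                                      GenomicRanges::reduce(gr_db[recs]))
    covered <- sum(GenomicRanges::width(inter))
    frac <- covered / call_len
    # pairwise overlap widths by plain interval arithmetic
    w_int <- pmax(0, pmin(calls$end_bp[ci], db_end[recs]) -
                    pmax(calls$start_bp[ci], db_start[recs]))
    full <- switch(mode,
      union = covered >= call_len,
      single_record = any(w_int >= call_len),
      reciprocal = any(w_int / call_len >= reciprocal &
                         w_int / (db_end[recs] - db_start[recs]) >=
                           reciprocal))
    res$overlap_fraction[ci] <- frac
    res$overlap_class[ci] <- if (full) "full" else if (frac > 0) "partial"
      else "none"
    if ("id" %in% names(db))
      res$overlap_ids[ci] <- paste(db$id[recs], collapse = ",")
  }
  dplyr::bind_cols(calls, res)
}

#' Attribute call bases to coding vs non-coding sequence
#'
#' Gene intervals are merged (overlaps unioned) before intersection, so a
#' base covered by several genes is counted once. For each call,
#' `coding_bp` is the number of bases intersecting the merged gene set and
#' `noncoding_bp = length_bp - coding_bp`.
#'
#' @param calls CNV call tibble.
#' @param genes Gene/coding-region interval tibble (`chrom`,
#'   `start`/`start_bp`, `end`/`end_bp`).
#' @return `calls` with `coding_bp` and `noncoding_bp` columns.
#' @export
coding_attribution <- function(calls, genes) {
  stopifnot_cols(calls, c("chrom", "start_bp", "end_bp"), "calls")
  n <- nrow(calls)
  if (n == 0 || is.null(genes) || nrow(genes) == 0) {
    return(mutate(calls, coding_bp = 0,
                  noncoding_bp = .data$end_bp - .data$start_bp))
  }
  gr_calls <- as_granges0(calls)
  merged <- GenomicRanges::reduce(records_granges(genes))
  # merged is disjoint, so summing pairwise intersections per call gives the
  # union coverage; identical calls in different samples each count in full
  # (suppressed warning: disjoint chromosome sets are a legitimate "no hit")
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_calls, merged))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  m_start <- GenomicRanges::start(merged)[sh] - 1  # back to 0-based
  m_end <- GenomicRanges::end(merged)[sh]
  w <- pmax(0, pmin(calls$end_bp[qh], m_end) -
              pmax(calls$start_bp[qh], m_start))
  coding <- rep(0, n)
  agg <- tapply(w, qh, sum)
  coding[as.integer(names(agg))] <- as.numeric(agg)
  mutate(calls, coding_bp = coding,
         noncoding_bp = .data$end_bp - .data$start_bp - coding)
}

#' Number of gene-overlapping calls
#'
#' A call counts as gene-overlapping when at least one of its bases
#' intersects the merged gene set (`coding_bp > 0`).
#'
#' @param calls CNV call tibble (attributed with [coding_attribution()] if
#'   `genes` is NULL).
#' @param genes Optional gene interval tibble; when supplied, attribution is
#'   computed here.
#' @return Integer count.
#' @export
count_gene_overlapping_calls <- function(calls, genes = NULL) {
  if (!"coding_bp" %in% names(calls))
    calls <- coding_attribution(calls, genes)
  sum(calls$coding_bp > 0)
}
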