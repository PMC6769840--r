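# Tabular genomic IO. All on-disk and in-memory coordinates are 0-based
# half-open (BED convention); human-readable printing elsewhere is 1-based.

# validate intervals after reading; `offset` = header lines before row 1
check_intervals <- function(df, path, start_col, end_col, offset = 1) {
  bad <- which(!is.finite(df[[start_col]]) | !is.finite(df[[end_col]]) |
                 df[[end_col]] <= df[[start_col]] | df[[start_col]] < 0)
  if (length(bad) > 0)
    abort(sprintf(
      "%s: invalid interval (end <= start, negative or non-numeric) at line %d",
      path, bad[1] + offset))
  invisible(df)
}

read_tsv_quiet <- function(path, col_types) {
  df <- readr::read_tsv(path, col_types = col_types, progress = FALSE,
                        na = c("", "NA", "."))
  prob <- readr::problems(df)
  if (nrow(prob) > 0)
    abort(sprintf("%s: malformed line %d (%s)", path, prob$row[1] + 1,
                  prob$expected[1]))
  df
}

#' Read / write a bin grid
#'
#' TSV with header `chrom`, `start`, `end`, `gc`, `usable`; coordinates
#' 0-based half-open. Reading is gzip-transparent.
#'
#' @param path File path.
#' @return `read_bin_grid()`: a bin grid tibble.
#' @export
read_bin_grid <- function(path) {
  df <- read_tsv_quiet(path, readr::cols(
    chrom = readr::col_character(), start = readr::col_double(),
    end = readr::col_double(), gc = readr::col_double(),
    usable = readr::col_logical()))
  check_intervals(df, path, "start", "end")
  if (any(df$gc < 0 | df$gc > 1, na.rm = TRUE))
    abort(sprintf("%s: gc fraction outside [0, 1]", path))
  df
}

#' @rdname read_bin_grid
#' @param grid A bin grid tibble.
#' @export
write_bin_grid <- function(grid, path) {
  stopifnot_cols(grid, c("chrom", "start", "end", "gc", "usable"), "grid")
  readr::write_tsv(grid, path, progress = FALSE)
  invisible(path)
}

#' Read / write per-bin counts
#'
#' TSV with header `chrom`, `start`, `end`, `count` and optional `sample_id`.
#'
#' @param path File path.
#' @return `read_bin_counts()`: a tibble aligned to the bin grid order used
#'   to write it.
#' @export
read_bin_counts <- function(path) {
  df <- read_tsv_quiet(path, readr::cols(
    chrom = readr::col_character(), start = readr::col_double(),
    end = readr::col_double(), count = readr::col_double(),
    .default = readr::col_character()))
  check_intervals(df, path, "start", "end")
  if (any(df$count < 0, na.rm = TRUE))
    abort(sprintf("%s: negative count", path))
  df
}

#' @rdname read_bin_counts
#' @param counts A counts tibble (from [simulate_sample()] or
#'   [bin_read_positions()]).
#' @export
write_bin_counts <- function(counts, path) {
  stopifnot_cols(counts, c("chrom", "start", "end", "count"), "counts")
  keep <- intersect(c("sample_id", "chrom", "start", "end", "count"),
                    names(counts))
  readr::write_tsv(counts[keep], path, progress = FALSE)
  invisible(path)
}

#' Read / write BED-like interval files
#'
#' Plain BED (no header) with 3+ tab-separated columns: `chrom`, `start`,
#' `end`, then optional columns taken from `extra_names` in order (default
#' `name`, `type`, `id`, `label`). A header line is auto-detected (second
#' field non-numeric) and used verbatim if present. Empty files yield an
#' empty tibble.
#'
#' @param path File path.
#' @param extra_names Names for columns beyond the first three when the file
#'   has no header.
#' @return A tibble with 0-based half-open `start`/`end`.
#' @export
read_bed <- function(path, extra_names = c("name", "type", "id", "label")) {
  first <- readr::read_lines(path, n_max = 1, progress = FALSE)
  if (length(first) == 0)
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  fields <- strsplit(first, "\t", fixed = TRUE)[[1]]
  has_header <- length(fields) >= 3 &&
    is.na(suppressWarnings(as.numeric(fields[2])))
  if (has_header) {
    df <- read_tsv_quiet(path, readr::cols(
      start = readr::col_double(), end = readr::col_double(),
      .default = readr::col_character()))
  } else {
    nms <- c("chrom", "start", "end",
             head(extra_names, max(0, length(fields) - 3)))
    df <- readr::read_tsv(path, col_names = nms, col_types = readr::cols(
      start = readr::col_double(), end = readr::col_double(),
      .default = readr::col_character()), progress = FALSE)
    prob <- readr::problems(df)
    if (nrow(prob) > 0)
      abort(sprintf("%s: malformed line %d", path, prob$row[1]))
  }
  check_intervals(df, path, "start", "end", offset = as.integer(has_header))
  df
}

#' @rdname read_bed
#' @param intervals Tibble with `chrom`, `start`, `end` and optional extra
#'   columns.
#' @param header Write a header line (TSV dialect) or plain headerless BED.
#' @export
write_bed <- function(intervals, path, header = FALSE) {
  stopifnot_cols(intervals, c("chrom", "start", "end"), "intervals")
  readr::write_tsv(intervals, path, col_names = header, progress = FALSE)
  invisible(path)
}

#' Read / write CNV call tables
#'
#' TSV with header `sample_id`, `chrom`, `start_bp`, `end_bp`, `type`,
#' `mean_ratio` plus any annotation columns; round-trips [call_cnvs()]
#' output.
#'
#' @param path File path.
#' @export
read_cnv_calls <- function(path) {
  df <- read_tsv_quiet(path, readr::cols(
    start_bp = readr::col_double(), end_bp = readr::col_double(),
    mean_ratio = readr::col_double(), .default = readr::col_character()))
  if (nrow(df) == 0) return(df)
  check_intervals(df, path, "start_bp", "end_bp")
  mutate(df, length_bp = .data$end_bp - .data$start_bp,
         length_kbp = .data$length_bp / 1000)
}

#' @rdname read_cnv_calls
#' @param calls A CNV call tibble.
#' @export
write_cnv_calls <- function(calls, path) {
  stopifnot_cols(calls, c("sample_id", "chrom", "start_bp", "end_bp", "type",
                          "mean_ratio"), "calls")
  drop <- intersect(c("length_bp", "length_kbp"), names(calls))
  readr::write_tsv(calls[setdiff(names(calls), drop)], path, progress = FALSE)
  invisible(path)
}

#' Count read start positions into bins
#'
#' Each read increments exactly the bin with `start <= pos < end` on its
#' chromosome. Reads on chromosomes absent from the grid, or beyond the last
#' bin, are tallied as unassigned (attribute `"unassigned"`), never an error.
#'
#' @param reads Tibble with columns `chrom` and `pos` (0-based read start).
#' @param grid Bin grid tibble.
#' @param sample_id Identifier stored in the output.
#' @return Counts tibble (grid columns plus `sample_id`, `count`) with
#'   attribute `unassigned` (number of reads not falling in any bin). The
#'   binning conserves reads: `sum(count) + unassigned == nrow(reads)`.
#' @examples
#' grid <- tibble::tibble(chrom = "chr1", start = c(0, 20000),
#'                        end = c(20000, 40000), gc = 0.5, usable = TRUE)
#' reads <- tibble::tibble(chrom = "chr1", pos = c(5, 19999, 20001))
#' bin_read_positions(reads, grid)$count
#' @export
bin_read_positions <- function(reads, grid, sample_id = "S1") {
  stopifnot_cols(reads, c("chrom", "pos"), "reads")
  stopifnot_cols(grid, c("chrom", "start", "end"), "grid")
  if (any(reads$pos < 0)) abort("read positions must be non-negative")
  count <- integer(nrow(grid))
  unassigned <- 0L
  grid_chroms <- split(seq_len(nrow(grid)), grid$chrom)
  for (ch in unique(reads$chrom)) {
    pos <- reads$pos[reads$chrom == ch]
    rows <- grid_chroms[[ch]]
    if (is.null(rows)) {
      unassigned <- unassigned + length(pos)
      next
    }
    starts <- grid$start[rows]
    ends <- grid$end[rows]
    k <- findInterval(pos, starts)  # bins sorted within chromosome
    inside <- k >= 1 & pos < ends[pmax(k, 1)]
    unassigned <- unassigned + sum(!inside)
    tab <- tabulate(k[inside], nbins = length(rows))
    count[rows] <- count[rows] + tab
  }
  out <- grid
  out$sample_id <- sample_id
  out$count <- count
  out <- select(out, "sample_id", dplyr::everything())
  attr(out, "unassigned") <- unassigned
  out
}

#' Compute bin GC content from a reference FASTA
#'
#' Sets each bin's `gc` to (G+C)/(A+C+G+T), case-insensitively, and marks
#' bins with more than 50% N unusable (`gc` = NA).
#'
#' @param grid Bin grid tibble (the `gc`/`usable` columns are overwritten).
#' @param fasta_path Path to a FASTA file containing every grid chromosome.
#' @return The grid with recomputed `gc` and `usable`.
#' @export
gc_from_fasta <- function(grid, fasta_path) {
  stopifnot_cols(grid, c("chrom", "start", "end"), "grid")
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  missing <- setdiff(unique(grid$chrom), names(seqs))
  if (length(missing) > 0)
    abort(sprintf("chromosome(s) missing from FASTA: %s",
                  paste(missing, collapse = ", ")))
  gc <- numeric(nrow(grid))
  usable <- logical(nrow(grid))
  for (ch in unique(grid$chrom)) {
    rows <- which(grid$chrom == ch)
    if (any(grid$end[rows] > length(seqs[[ch]])))
      abort(sprintf("bins on %s extend beyond the sequence end", ch))
    v <- Biostrings::Views(seqs[[ch]],
                           start = grid$start[rows] + 1,
                           end = grid$end[rows])
    freq <- Biostrings::letterFrequency(v, c("A", "C", "G", "T", "N"))
    acgt <- rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
    width <- grid$end[rows] - grid$start[rows]
    ok <- freq[, "N"] <= 0.5 * width & acgt > 0
    gc[rows] <- ifelse(ok, rowSums(freq[, c("G", "C"), drop = FALSE]) / acgt,
                       NA_real_)
    usable[rows] <- ok
  }
  out <- grid
  out$gc <- gc
  out$usable <- usable
  out
}
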