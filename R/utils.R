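# internal helpers

# Round half away from zero (printed-report convention; base round() is
# banker's rounding).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate `code` after set.seed(seed), restoring the caller's RNG state.
# seed = NULL leaves the RNG stream alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# derive a reproducible sub-seed (< 2^31) from a base seed and integer tags
derive_seed <- function(seed, ...) {
  tags <- c(seed, ...)
  h <- 0
  for (t in tags) h <- (h * 48271 + as.double(t) %% 2147483647) %% 2147483647
  as.integer(h)
}

stopifnot_cols <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0)
    abort(sprintf("`%s` is missing required column(s): %s", what,
                  paste(miss, collapse = ", ")))
  invisible(df)
}

# natural chromosome ordering: chr1 < chr2 < ... < chr10 < chrX-style labels
chrom_order <- function(chrom) {
  u <- unique(as.character(chrom))
  num <- suppressWarnings(as.numeric(sub("^chr", "", u)))
  u[order(is.na(num), num, u)]
}

# 0-based half-open intervals -> GRanges (IRanges is 1-based inclusive)
as_granges0 <- function(df, start_col = "start_bp", end_col = "end_bp") {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df[[start_col]] + 1, end = df[[end_col]])
  )
}
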