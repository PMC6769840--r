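# Independent oracles and tiny fixture builders shared across tests.

# Exhaustive O(n^2) search over all admissible circular arcs, written
# directly from the t-statistic definition (independent of the package's
# prefix-sum scan). Same tie-break contract: a later arc must improve t^2 by
# a relative 1e-10.
brute_max_arc_t <- function(x, w = 2) {
  n <- length(x)
  best <- list(i = 0L, j = min(w, n), t = 0)
  best_t2 <- -1
  for (i in 0:(n - 1)) {
    jmax <- min(n, i + n - w)
    if (i + w > jmax) next
    for (j in seq(i + w, jmax)) {
      arc <- x[(i + 1):j]
      comp <- x[-((i + 1):j)]
      k <- length(arc)
      m <- length(comp)
      ss <- sum((arc - mean(arc))^2) + sum((comp - mean(comp))^2)
      sp2 <- ss / (n - 2)
      d <- mean(arc) - mean(comp)
      t2 <- if (sp2 <= 0) {
        if (d == 0) 0 else 1e300
      } else {
        d^2 / (sp2 * (1 / k + 1 / m))
      }
      if (t2 > best_t2 * (1 + 1e-10)) {
        best_t2 <- t2
        best <- list(i = i, j = j,
                     t = sign(d) * (if (t2 >= 1e300) 1e150 else sqrt(t2)))
      }
    }
  }
  best
}

# uniform-GC test grid, all usable
toy_grid <- function(n_bins, bin = 20000, gc = 0.5, chrom = "chr1") {
  tibble::tibble(chrom = chrom, start = (seq_len(n_bins) - 1) * bin,
                 end = seq_len(n_bins) * bin,
                 gc = rep_len(gc, n_bins), usable = TRUE)
}

toy_counts <- function(grid, counts, sample_id = "S1") {
  out <- grid
  out$sample_id <- sample_id
  out$count <- as.integer(rep_len(counts, nrow(grid)))
  out
}

# a flat normalized profile tibble
toy_profile <- function(ratio, bin = 20000, chrom = "chr1") {
  n <- length(ratio)
  tibble::tibble(chrom = chrom, start = (seq_len(n) - 1) * bin,
                 end = seq_len(n) * bin, ratio = ratio)
}
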