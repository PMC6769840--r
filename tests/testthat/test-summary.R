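two_calls <- function() {
  tibble::tibble(sample_id = c("a", "b"), chrom = "chr2",
                 start_bp = 0, end_bp = 1e6, type = "gain",
                 mean_ratio = 1.5)
}

test_that("reciprocal-overlap clustering groups recurrent variants", {
  cl <- cluster_variants(two_calls(), cohort_size = 100)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_events, 2L)
  expect_equal(cl$frequency, 0.02)
  expect_equal(cl$members[[1]], c("a", "b"))

  # disjoint calls stay singletons; same-position different-type too
  calls <- tibble::tibble(
    sample_id = c("a", "b", "c"), chrom = "chr1",
    start_bp = c(0, 5e6, 5e6), end_bp = c(1e6, 6e6, 6e6),
    type = c("gain", "gain", "loss"), mean_ratio = c(1.5, 1.5, 0.5))
  cl2 <- cluster_variants(calls, cohort_size = 10)
  expect_equal(nrow(cl2), 3)
  expect_equal(sum(cl2$n_events), nrow(calls))

  # 55% mutual overlap joins at threshold 0.5, not at 0.6
  pair <- tibble::tibble(sample_id = c("a", "b"), chrom = "chr1",
                         start_bp = c(0, 0.45e6), end_bp = c(1e6, 1.45e6),
                         type = "loss", mean_ratio = 0.5)
  expect_equal(nrow(cluster_variants(pair, 10, reciprocal_overlap = 0.5)), 1)
  expect_equal(nrow(cluster_variants(pair, 10, reciprocal_overlap = 0.6)), 2)

  expect_error(cluster_variants(two_calls(), cohort_size = 1),
               "cohort_size")
})

test_that("single linkage chains overlapping same-type calls", {
  # a-b and b-c overlap reciprocally, a-c do not: one cluster of three
  chain <- tibble::tibble(
    sample_id = c("a", "b", "c"), chrom = "chr1",
    start_bp = c(0, 4e5, 8e5), end_bp = c(1e6, 1.4e6, 1.8e6),
    type = "gain", mean_ratio = 1.5)
  cl <- cluster_variants(chain, 10, reciprocal_overlap = 0.5)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_carriers, 3L)
})

test_that("every call lands in exactly one cluster (random cohorts)", {
  withr::with_seed(37, {
    calls <- tibble::tibble(
      sample_id = sample(sprintf("S%02d", 1:40), 120, TRUE),
      chrom = sample(sprintf("chr%d", 1:4), 120, TRUE),
      start_bp = sample(seq(0, 5e7, 2e5), 120, TRUE),
      type = sample(c("gain", "loss"), 120, TRUE), mean_ratio = 1.5)
    calls$end_bp <- calls$start_bp + sample(c(6e5, 1e6, 3e6), 120, TRUE)
  })
  cl <- cluster_variants(calls, cohort_size = 60)
  expect_equal(sum(cl$n_events), nrow(calls))
  expect_true(all(cl$frequency > 0 & cl$frequency <= 1))
  expect_true(all(cl$n_carriers <= cl$n_events))
})

test_that("cohort percentages are exact arithmetic on the printed scale", {
  # 178 gains / 47 losses -> 79.11% / 20.89%; carriers 212 / 5018 -> 4.2%
  calls <- tibble::tibble(
    sample_id = sprintf("S%03d", 1:225), chrom = "chr1",
    start_bp = (0:224) * 2e6, end_bp = (0:224) * 2e6 + 8e5,
    type = rep(c("gain", "loss"), c(178, 47)), mean_ratio = 1.5)
  calls$sample_id[213:225] <- sprintf("S%03d", 1:13)  # 212 distinct carriers
  s <- summarize_cohort(calls, cohort_size = 5018)
  expect_equal(s$pct_gain, 79.11)
  expect_equal(s$pct_loss, 20.89)
  expect_equal(s$pct_gain + s$pct_loss, 100)
  expect_equal(s$gain_loss_ratio, 3.8)
  expect_equal(s$n_carriers, 212L)
  expect_equal(s$pct_carriers, 4.2)
  expect_equal(sum(s$per_chrom$gain, s$per_chrom$loss), 225)

  g <- glance(s)
  expect_equal(g$n_calls, 225L)
  expect_equal(g$pct_gain, 79.11)
  td <- tidy(s)
  expect_true(all(c("statistic", "value") %in% names(td)))
})

test_that("an empty call set summarizes to zeros, not an error", {
  empty <- tibble::tibble(sample_id = character(), chrom = character(),
                          start_bp = numeric(), end_bp = numeric(),
                          type = character())
  s <- summarize_cohort(empty, cohort_size = 100)
  expect_equal(s$n_calls, 0)
  expect_equal(s$pct_gain, 0)
  expect_equal(s$n_carriers, 0L)
  expect_equal(s$sizes$median_kbp, 0)
  expect_equal(nrow(mbp_table(empty)), 3)
  expect_equal(mbp_table(empty)$total_mbp, c(0, 0, 0))
})

test_that("the Mbp table is row- and column-additive", {
  calls <- tibble::tibble(
    sample_id = c("a", "b", "c"), chrom = "chr1",
    start_bp = c(0, 3e6, 8e6), end_bp = c(1e6, 4.5e6, 8.8e6),
    type = c("gain", "gain", "loss"), mean_ratio = c(1.5, 1.5, 0.5),
    coding_bp = c(2e5, 0, 1e5))
  tab <- mbp_table(calls)
  expect_equal(tab$type, c("gain", "loss", "total"))
  expect_equal(tab$n, c(2L, 1L, 3L))
  expect_equal(tab$total_mbp, c(2.5, 0.8, 3.3))
  expect_equal(tab$coding_mbp + tab$noncoding_mbp, tab$total_mbp)
  expect_equal(tab$total_mbp[3], sum(tab$total_mbp[1:2]))

  s <- summarize_cohort(calls, cohort_size = 10)
  expect_equal(s$coding$n_gene_overlapping, 2)
  expect_equal(s$coding$pct_coding_overall,
               round(100 * 0.3 / 3.3, 2))
})

test_that("cytoband labels attach by interval midpoint, coordinates otherwise", {
  bands <- tibble::tibble(chrom = c("chr2", "chr2", "chr3"),
                          start = c(0, 3e7, 0), end = c(3e7, 9e7, 5e7),
                          name = c("p22", "p21", "q26.3"))
  cl <- tibble::tibble(chrom = c("chr2", "chr3", "chr9"),
                       start_bp = c(3.66e7, 1e6, 0),
                       end_bp = c(3.73e7, 2e6, 1e6))
  out <- label_cytobands(cl, bands)
  expect_equal(out$cytoband, c("2p21", "3q26.3", NA))
  # midpoint on the first-band side
  out2 <- label_cytobands(tibble::tibble(chrom = "chr2", start_bp = 2.8e7,
                                         end_bp = 3.0e7), bands)
  expect_equal(out2$cytoband, "2p22")
})

test_that("autoplot and plot helpers return ggplot objects", {
  ref <- synthetic_reference_cohort()
  s <- summarize_cohort(ref$calls, ref$cohort_size)
  expect_s3_class(autoplot(s), "ggplot")
  expect_s3_class(autoplot(s, type = "chromosomes"), "ggplot")
  expect_s3_class(plot_size_distribution(ref$calls), "ggplot")
  prof <- toy_profile(c(rep(1, 50), rep(1.5, 30), rep(1, 20)))
  segs <- tibble::tibble(chrom = "chr1", start_bp = 50 * 20000,
                         end_bp = 80 * 20000, mean_ratio = 1.5)
  expect_s3_class(plot_profile(prof, segs), "ggplot")
})
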