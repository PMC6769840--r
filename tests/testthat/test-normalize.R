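test_that("retained bins are the usable, non-empty ones", {
  grid <- toy_grid(3)
  cnt <- toy_counts(grid, c(0L, 5L, 7L))
  expect_equal(filter_empty_bins(cnt, grid), c(2L, 3L))

  cnt2 <- toy_counts(grid, c(1L, 5L, 7L))
  expect_equal(filter_empty_bins(cnt2, grid), 1:3)

  # unusable bin is excluded even with a high count
  grid3 <- grid
  grid3$usable[3] <- FALSE
  cnt3 <- toy_counts(grid3, c(2L, 5L, 9L))
  expect_equal(filter_empty_bins(cnt3, grid3), c(1L, 2L))

  expect_error(filter_empty_bins(toy_counts(grid, 0L), grid), "unusable")
})

test_that("LOESS detrending corrects a perfectly collinear GC trend to the mean", {
  grid <- toy_grid(36, gc = c(0.3, 0.4, 0.5))
  cnt <- toy_counts(grid, c(80L, 100L, 120L))
  res <- loess_gc_correct(cnt, grid, span = 0.75)
  expect_equal(res$corrected$corrected, rep(100, 36), tolerance = 1e-8)
  expect_equal(res$model$rc_global, 100)

  # identical GC everywhere is degenerate
  gridc <- toy_grid(40, gc = 0.5)
  expect_error(loess_gc_correct(toy_counts(gridc, 100L), gridc),
               "degenerate GC")
  expect_error(loess_gc_correct(toy_counts(toy_grid(10), 5L), toy_grid(10)),
               ">= 30")
})

test_that("GC correction preserves the retained-bin mean identity", {
  spec <- simulation_spec(n_chromosomes = 1, chromosome_length_bp = 4e7,
                          artifact_rank = 0, dropout_fraction = 0, seed = 21)
  grid <- simulate_bin_grid(spec)
  s <- simulate_sample(grid, spec, seed = 22)
  res <- loess_gc_correct(s, grid)
  keep <- res$model$retained
  lhs <- mean(res$corrected$corrected[keep])
  rhs <- res$model$rc_global +
    (mean(s$count[keep]) - mean(res$model$fitted))
  expect_equal(lhs, rhs, tolerance = 1e-6)
})

test_that("GC correction removes most of the count-GC slope", {
  spec <- simulation_spec(n_chromosomes = 1, chromosome_length_bp = 1e8,
                          artifact_rank = 0, dropout_fraction = 0, seed = 31)
  grid <- simulate_bin_grid(spec)
  s <- simulate_sample(grid, spec, seed = 32)
  pre <- unname(coef(lm(s$count ~ grid$gc))[2])
  res <- loess_gc_correct(s, grid)
  post <- unname(coef(lm(res$corrected$corrected ~ grid$gc))[2])
  expect_gt(abs(pre), 10)  # the default bias curve induces a real slope
  expect_lt(abs(post), 0.05 * abs(pre))
})

test_that("low-coverage bins are masked against the control mean", {
  m <- rbind(c(100, 100, 5), c(100, 100, 5))
  expect_equal(mask_low_coverage_bins(m), c(TRUE, TRUE, FALSE))
  expect_equal(mask_low_coverage_bins(rbind(rep(7, 4), rep(7, 4))),
               rep(TRUE, 4))
  # zero-mean bin always masked
  m0 <- rbind(c(50, 0, 60), c(70, 0, 40))
  expect_equal(mask_low_coverage_bins(m0)[2], FALSE)
  expect_error(mask_low_coverage_bins(m[1, , drop = FALSE]), "2 control")
})

test_that("PCA reference captures a constructed rank-1 artifact", {
  spec <- simulation_spec(n_chromosomes = 1, chromosome_length_bp = 4e7,
                          mean_reads_per_bin = 800,
                          artifact_rank = 1, artifact_scale = 0.08,
                          dropout_fraction = 0, seed = 41)
  grid <- simulate_bin_grid(spec)
  co <- simulate_cohort(grid, spec, n_samples = 50, seed = 42)
  ref <- fit_pca_reference(co$counts, grid, n_components = 1)
  pattern <- co$artifact[1, ref$mask]
  cosine <- sum(ref$rotation[1, ] * pattern) /
    sqrt(sum(ref$rotation[1, ]^2) * sum(pattern^2))
  expect_gt(abs(cosine), 0.99)

  expect_error(fit_pca_reference(co$counts, grid, n_components = 50),
               "smaller than the number of controls")
})

test_that("identical controls give a null reference and K = 0 is identity", {
  grid <- toy_grid(200, gc = seq(0.3, 0.6, length.out = 200))
  base <- as.integer(round(150 + 50 * grid$gc))
  counts <- dplyr::bind_rows(lapply(1:5, function(s)
    toy_counts(grid, base, sample_id = sprintf("C%d", s))))
  ref <- fit_pca_reference(counts, grid, n_components = 2)
  expect_lt(max(ref$sdev), 1e-8)  # no variance to explain

  # removal is a no-op on another identical sample
  cor1 <- loess_gc_correct(toy_counts(grid, base), grid)
  prof <- pca_normalize(cor1, ref, grid)
  ref0 <- fit_pca_reference(counts, grid, n_components = 0)
  prof0 <- pca_normalize(cor1, ref0, grid)
  expect_equal(prof$ratio, prof0$ratio, tolerance = 1e-10)

  # K = 0: ratio is corrected counts over their mean
  cc <- cor1$corrected$corrected
  expect_equal(prof0$ratio[prof0$mask], (cc / mean(cc))[prof0$mask],
               tolerance = 1e-12)
})

test_that("PCA normalization flattens artifacts but preserves CNV signal", {
  spec <- simulation_spec(n_chromosomes = 2, chromosome_length_bp = 3e7,
                          mean_reads_per_bin = 2000,
                          artifact_rank = 2, artifact_scale = 0.03,
                          dropout_fraction = 0, seed = 51)
  grid <- simulate_bin_grid(spec)
  co <- simulate_cohort(grid, spec, n_samples = 40, seed = 52)
  ref <- fit_pca_reference(co$counts, grid, n_components = 2)

  # noiseless construction: control mean times the artifact term exactly as
  # it manifests in corrected profiles; after projection the profile must
  # coincide with the artifact-free sample's (fixed per-bin structure,
  # identical in both, cancels) and sit close to 1 throughout
  a <- spec$artifact_scale * as.numeric(c(2, -1.5) %*% co$artifact)
  fake0 <- grid
  fake0$corrected <- 200 * ref$bin_mean
  fake0$sample_id <- "T0"
  fake1 <- dplyr::mutate(fake0, corrected = .data$corrected * exp(a))
  p0 <- pca_normalize(fake0, ref, grid)
  p1 <- pca_normalize(fake1, ref, grid)
  expect_lt(max(abs(p1$ratio[p1$mask] - p0$ratio[p0$mask])), 0.05)
  expect_lt(quantile(abs(p1$ratio[p1$mask] - 1), 0.99), 0.05)

  # +0.5 shift over 40 bins survives denoising
  ev <- tibble::tibble(chrom = "chr2", start_bp = 400 * 20000,
                       end_bp = 440 * 20000, type = "gain",
                       ratio_shift = 0.5)
  withr::with_seed(54, {
    s_ev <- simulate_sample(grid, spec, events = ev,
                            artifact = list(patterns = co$artifact,
                                            loading = c(-1, 1)),
                            sample_id = "T1")
  })
  p_ev <- normalize_profile(s_ev, grid, ref)
  reg <- p_ev$chrom == "chr2" & p_ev$start >= ev$start_bp &
    p_ev$end <= ev$end_bp & p_ev$mask
  expect_equal(mean(p_ev$ratio[reg]), 1.5, tolerance = 0.05 / 1.5)
  expect_equal(mean(p_ev$ratio[!reg & p_ev$mask]), 1, tolerance = 0.02)
})

test_that("residual control variance is non-increasing in K and the pipeline is deterministic", {
  spec <- simulation_spec(n_chromosomes = 1, chromosome_length_bp = 3e7,
                          artifact_rank = 3, artifact_scale = 0.05,
                          dropout_fraction = 0, seed = 61)
  grid <- simulate_bin_grid(spec)
  co <- simulate_cohort(grid, spec, n_samples = 20, seed = 62)
  one <- dplyr::filter(co$counts, sample_id == "S0001")
  vars <- vapply(0:4, function(k) {
    ref <- fit_pca_reference(co$counts, grid, n_components = k)
    p <- normalize_profile(one, grid, ref)
    var(p$ratio[p$mask])
  }, numeric(1))
  expect_true(all(diff(vars) <= 1e-12))

  # no hidden randomness anywhere in normalization
  ref <- fit_pca_reference(co$counts, grid, n_components = 3)
  expect_identical(normalize_profile(one, grid, ref),
                   normalize_profile(one, grid, ref))
})
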