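test_that("bin grid tiles chromosomes, drops partial bins, honours dropout", {
  spec <- simulation_spec(n_chromosomes = 1, chromosome_length_bp = 1e6,
                          bin_size_bp = 20000, dropout_fraction = 0)
  grid <- simulate_bin_grid(spec)
  expect_equal(nrow(grid), 50)
  expect_true(all(grid$end - grid$start == 20000))
  expect_true(all(grid$usable))
  expect_true(all(grid$gc > 0 & grid$gc < 1))

  # partial trailing bin dropped
  spec2 <- simulation_spec(n_chromosomes = 2,
                           chromosome_length_bp = c(1e6 + 19999, 5e5))
  grid2 <- simulate_bin_grid(spec2)
  expect_equal(sum(grid2$chrom == "chr1"), 50)
  expect_equal(sum(grid2$chrom == "chr2"), 25)

  # determinism: same spec + seed -> identical grid
  expect_identical(simulate_bin_grid(spec2), simulate_bin_grid(spec2))

  spec3 <- simulation_spec(n_chromosomes = 1, chromosome_length_bp = 2e7,
                           dropout_fraction = 0.1, seed = 9)
  grid3 <- simulate_bin_grid(spec3)
  expect_gt(sum(!grid3$usable), 0)
  expect_lt(mean(!grid3$usable), 0.2)
})

test_that("simulation_spec validates its inputs", {
  expect_error(simulation_spec(bin_size_bp = 0), "bin_size_bp")
  expect_error(simulation_spec(chromosome_length_bp = -1),
               "chromosome_length_bp")
  expect_error(simulation_spec(dropout_fraction = 1), "dropout_fraction")
  expect_error(simulation_spec(gc_bias = function(g) g - 0.5), "gc_bias")
})

test_that("simulated counts follow the specified Poisson means", {
  spec <- simulation_spec(n_chromosomes = 1, chromosome_length_bp = 1e8,
                          mean_reads_per_bin = 171, gc_bias = gc_bias_flat(),
                          artifact_rank = 0, dropout_fraction = 0, seed = 3)
  grid <- simulate_bin_grid(spec)
  s <- simulate_sample(grid, spec, seed = 4)
  n <- nrow(s)
  expect_equal(n, 5000)
  se <- sqrt(171 / n)
  expect_lt(abs(mean(s$count) - 171), 3 * se)

  # a +0.5 gain raises the regional mean by a factor ~1.5
  ev <- tibble::tibble(chrom = "chr1", start_bp = 100 * 20000,
                       end_bp = 150 * 20000, type = "gain",
                       ratio_shift = 0.5)
  s2 <- simulate_sample(grid, spec, events = ev, seed = 5)
  inside <- mean(s2$count[101:150])
  outside <- mean(s2$count[-(101:150)])
  # se of the regional ratio ~ sqrt(1.5/ (171*50)) ~ 0.013
  expect_lt(abs(inside / outside - 1.5), 3 * sqrt(1.5 / (171 * 50)) + 0.01)

  # zero expected coverage -> all-zero counts
  spec0 <- simulation_spec(n_chromosomes = 1, chromosome_length_bp = 1e6,
                           mean_reads_per_bin = 0, artifact_rank = 0)
  g0 <- simulate_bin_grid(spec0)
  expect_true(all(simulate_sample(g0, spec0, seed = 1)$count == 0))
})

test_that("per-bin means converge over replicates (law of large numbers)", {
  spec <- simulation_spec(n_chromosomes = 1, chromosome_length_bp = 1e6,
                          mean_reads_per_bin = 100, gc_bias = gc_bias_flat(),
                          artifact_rank = 0, dropout_fraction = 0)
  grid <- simulate_bin_grid(spec)
  reps <- 400
  sums <- numeric(nrow(grid))
  withr::with_seed(11, {
    for (r in seq_len(reps)) sums <- sums + simulate_sample(grid, spec)$count
  })
  per_bin_mean <- sums / reps
  se <- sqrt(100 / reps)
  expect_true(all(abs(per_bin_mean - 100) < 4 * se))
  expect_lt(abs(mean(per_bin_mean) - 100), 3 * se / sqrt(nrow(grid)))
})

test_that("event validation rejects inconsistent and conflicting events", {
  spec <- simulation_spec(n_chromosomes = 1, chromosome_length_bp = 2e6,
                          artifact_rank = 0, dropout_fraction = 0)
  grid <- simulate_bin_grid(spec)
  bad_sign <- tibble::tibble(chrom = "chr1", start_bp = 0, end_bp = 2e5,
                             type = "gain", ratio_shift = -0.5)
  expect_error(simulate_sample(grid, spec, events = bad_sign), "sign")
  clash <- tibble::tibble(chrom = "chr1",
                          start_bp = c(0, 1e5), end_bp = c(2e5, 3e5),
                          type = c("gain", "loss"),
                          ratio_shift = c(0.5, -0.5))
  expect_error(simulate_sample(grid, spec, events = clash), "overlapping")
  outside <- tibble::tibble(chrom = "chr9", start_bp = 0, end_bp = 2e5,
                            type = "gain", ratio_shift = 0.5)
  expect_error(simulate_sample(grid, spec, events = outside), "grid")
})

test_that("cohort assignment hits requested carrier frequencies", {
  spec <- simulation_spec(n_chromosomes = 1, chromosome_length_bp = 1e6,
                          mean_reads_per_bin = 5, artifact_rank = 0,
                          dropout_fraction = 0)
  grid <- simulate_bin_grid(spec)
  var <- tibble::tibble(chrom = "chr1", start_bp = 2e5, end_bp = 8e5,
                        type = "gain", ratio_shift = 0.5, frequency = 0.005)
  co <- simulate_cohort(grid, spec, n_samples = 1000, variants = var,
                        seed = 6)
  expect_equal(nrow(co$truth), 5)  # deterministic: round(0.005 * 1000)
  expect_equal(dplyr::n_distinct(co$truth$sample_id), 5)

  # no variants -> empty truth set
  co0 <- simulate_cohort(grid, spec, n_samples = 5, seed = 6)
  expect_equal(nrow(co0$truth), 0)

  bad <- dplyr::mutate(var, frequency = 1.5)
  expect_error(simulate_cohort(grid, spec, 10, variants = bad), "frequency")
  expect_error(simulate_cohort(grid, spec, 1), "n_samples")

  # determinism of the whole cohort
  co2 <- simulate_cohort(grid, spec, n_samples = 1000, variants = var,
                         seed = 6)
  expect_identical(co$counts, co2$counts)
  expect_identical(co$truth, co2$truth)
})
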