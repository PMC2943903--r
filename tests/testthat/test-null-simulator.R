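test_that("zero-error simulation yields exact genomic substrings, deterministically", {
  genome <- generate_genome(5000, seed = 51)
  reads <- simulate_reads(genome, 200, 25, error_profile = 0, seed = 7)
  haystack <- paste0(genome$seq, "#", as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(genome$seq))))
  expect_true(all(vapply(reads$seq, grepl, logical(1), x = haystack,
                         fixed = TRUE)))

  again <- simulate_reads(genome, 200, 25, error_profile = 0, seed = 7)
  expect_identical(reads$seq, again$seq)
  expect_identical(reads$qual, again$qual)
  other <- simulate_reads(genome, 200, 25, error_profile = 0, seed = 8)
  expect_false(identical(reads$seq, other$seq))
})

test_that("a forced substitution position always differs from the template", {
  genome <- generate_genome(2000, seed = 52)
  prof <- c(0, 1, 0, 0, 0, 0, 0, 0, 0, 0)
  reads <- simulate_reads(genome, 300, 10, error_profile = prof, seed = 3)
  clean <- simulate_reads(genome, 300, 10, error_profile = 0, seed = 3)
  expect_true(all(substr(reads$seq, 2, 2) != substr(clean$seq, 2, 2)))
  expect_identical(substr(reads$seq, 3, 10), substr(clean$seq, 3, 10))
})

test_that("realised substitution rates match the error profile", {
  genome <- generate_genome(10000, seed = 53)
  prof <- rep(0.1, 15)
  clean <- simulate_reads(genome, 20000, 15, error_profile = 0, seed = 9)
  noisy <- simulate_reads(genome, 20000, 15, error_profile = prof, seed = 9)
  for (j in c(1, 8, 15)) {
    rate <- mean(substr(noisy$seq, j, j) != substr(clean$seq, j, j))
    expect_lt(abs(rate - 0.1), 4 * sqrt(0.1 * 0.9 / 20000))
  }
})

test_that("start positions are uniform over the genome across seeds", {
  genome <- generate_genome(20000, seed = 54)
  passed <- vapply(1:10, function(s) {
    reads <- simulate_reads(genome, 10000, 10, error_profile = 0, seed = s)
    starts <- as.integer(sub("^sim_\\d+:(\\d+):.*$", "\\1", reads$read_id))
    bins <- cut(starts, breaks = seq(0, 20000 - 10 + 1, length.out = 21))
    stats::chisq.test(table(bins))$p.value > 0.001
  }, logical(1))
  expect_gte(mean(passed), 0.95)
})

test_that("simulated qualities encode the error profile", {
  genome <- generate_genome(1000, seed = 55)
  prof <- c(0.1, 0.01, 0.001)
  reads <- simulate_reads(genome, 5, 3, error_profile = prof, seed = 2)
  expect_equal(phred_decode(reads$qual[1], 33)[[1]], c(10L, 20L, 30L))
  expect_error(simulate_reads(genome, 5, 2000), "shorter than")
})

test_that("two-replicate calibration equals the hand mean/sd of its matrices", {
  genome <- generate_genome(3000, seed = 56)
  cal <- calibrate_null(genome, n = 500, read_length = 10, error_profile = 0,
                        replicates = 2, k = 2, alpha = 0.5, min_coverage = 1,
                        seed = 100)
  m <- lapply(1:2, function(r) {
    reads <- simulate_reads(genome, 500, 10, error_profile = 0, seed = 100 + r)
    kl_matrix(count_kmers_by_position(reads, 2), alpha = 0.5,
              min_coverage = 1)$values
  })
  expect_equal(cal$mean, (m[[1]] + m[[2]]) / 2, tolerance = 1e-12)
  expect_equal(cal$sd, abs(m[[1]] - m[[2]]) / sqrt(2), tolerance = 1e-8)
  expect_error(calibrate_null(genome, 500, 10, replicates = 1), "at least 2")
})

test_that("the default replicate count is 100", {
  expect_equal(formals(calibrate_null)$replicates, 100L)
})

test_that("effect sizes standardise cells and flag degenerate ones", {
  pos <- 1:3
  mk <- function(v) {
    m <- matrix(v, 3, 3, dimnames = list(pos, pos)); diag(m) <- 0; m
  }
  cal <- structure(list(mean = mk(0.2), sd = mk(0.05), positions = pos,
                        replicates = 10L, k = 2L, alpha = 0.5,
                        avg_sd = 0.05, avg_sd_ci95 = c(lower = 0.04, upper = 0.06)),
                   class = "null_calibration")
  obs <- structure(list(values = mk(0.2), positions = pos, dropped = integer(),
                        k = 2L, alpha = 0.5), class = "kl_matrix")
  es <- effect_sizes(obs, cal)
  expect_true(all(es$z[row(es$z) != col(es$z)] == 0))

  obs2 <- obs; obs2$values <- mk(0.2 + 2 * 0.05)
  es2 <- effect_sizes(obs2, cal)
  expect_equal(es2$z[row(es2$z) != col(es2$z)], rep(2, 6), tolerance = 1e-12)
  # the zero-sd diagonal is reported degenerate, not given a number
  expect_equal(nrow(es2$degenerate), 3L)
  expect_true(all(is.na(diag(es2$z))))

  cal$positions <- 1:2
  expect_error(effect_sizes(obs, cal), "mismatch")
})

test_that("unbiased data scored against its own calibration stays within |z| < 4", {
  genome <- generate_genome(20000, seed = 57)
  reads <- generate_reads(genome, 10000, 12, seed = 58)
  obs <- kl_matrix(count_kmers_by_position(reads, 2), alpha = 0.5,
                   min_coverage = 1)
  cal <- calibrate_null(genome, n = 10000, read_length = 12, error_profile = 0,
                        replicates = 10, k = 2, alpha = 0.5, min_coverage = 1,
                        seed = 200)
  es <- effect_sizes(obs, cal)
  expect_gte(glance(es)$prop_abs_z_lt_4, 0.99)
})
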