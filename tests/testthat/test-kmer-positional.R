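test_that("positional k-mer counting matches hand fixtures and the N rule", {
  pk <- count_kmers_by_position(qc_reads("ACGT"), k = 2)
  expect_equal(dplyr::arrange(as.data.frame(pk), position),
               data.frame(position = 1:3, kmer = c("AC", "CG", "GT"),
                          count = rep(1L, 3)),
               ignore_attr = TRUE)

  pk2 <- count_kmers_by_position(qc_reads("ANGT"), k = 2)
  wc <- window_counts(pk2)
  expect_equal(wc$skipped, c(1L, 1L, 0L))
  expect_equal(pk2$kmer[pk2$position == 3], "GT")

  expect_error(count_kmers_by_position(qc_reads("ACG"), k = 4), "exceeds")
})

test_that("k = 1 reproduces the base-call counts for A, C, G, T", {
  reads <- random_reads(300, 12, with_n = TRUE, seed = 5)
  pk <- count_kmers_by_position(reads, k = 1)
  bc <- count_basecalls(reads)
  wide <- tidyr::pivot_wider(pk, names_from = "kmer", values_from = "count",
                             values_fill = 0L)
  for (b in c("A", "C", "G", "T")) {
    expect_equal(wide[[b]], bc[[b]])
  }
})

test_that("window conservation holds on random inputs", {
  for (seed in 1:3) {
    reads <- random_reads(150, 20, with_n = TRUE, seed = seed)
    pk <- count_kmers_by_position(reads, k = 3)
    per_pos <- dplyr::summarise(dplyr::group_by(pk, position),
                                total = sum(count), .groups = "drop")
    wc <- window_counts(pk)
    total <- per_pos$total[match(wc$position, per_pos$position)]
    total[is.na(total)] <- 0L
    expect_equal(total + wc$skipped, wc$n_windows)
  }
})

test_that("reference background models count windows on one or both strands", {
  bg <- background_from_reference("AAAT", k = 2)
  expect_equal(bg$prob[match(c("AA", "AT"), bg$kmer)], c(2 / 3, 1 / 3))
  expect_equal(attr(bg, "n_sites"), 3L)

  bg2 <- background_from_reference("AAAT", k = 2, both_strands = TRUE)
  expect_equal(bg2$prob[match(c("AA", "AT", "TT"), bg2$kmer)], rep(2 / 6, 3))

  expect_error(background_from_reference("NNNN", k = 2), "no valid windows")
  expect_error(background_from_reference("AC", k = 3), "shorter than k")
})

test_that("read-pool backgrounds pool counts over positions", {
  pk <- count_kmers_by_position(qc_reads("ACGT"), k = 2)
  bg <- background_from_reads(pk)
  expect_equal(sort(bg$kmer), c("AC", "CG", "GT"))
  expect_equal(bg$prob, rep(1 / 3, 3))

  one <- count_kmers_by_position(qc_reads(c("AAA", "AAA")), k = 3)
  expect_equal(background_from_reads(one)$prob, 1)
})

test_that("pooled read background approximates the reference at high coverage", {
  genome <- generate_genome(20000, seed = 21)
  reads <- generate_reads(genome, 40000, 30, seed = 22)
  pk <- count_kmers_by_position(reads, k = 3)
  pool <- background_from_reads(pk)
  ref <- background_from_reference(genome, k = 3, both_strands = TRUE)
  p <- ref$prob[match(all_kmers_vec(3), ref$kmer)]
  q <- pool$prob[match(all_kmers_vec(3), pool$kmer)]
  p[is.na(p)] <- 0; q[is.na(q)] <- 0
  expect_lt(sum(abs(p - q)) / 2, 0.01)   # total variation distance
})

test_that("an injected start motif is flagged as massively over-represented", {
  genome <- generate_genome(50000, seed = 31)
  reads <- generate_reads(genome, 20000, 30,
                          bias = bias_spec(start_motif = list(motif = "ACGTAC",
                                                              fraction = 0.05)),
                          seed = 32)
  pk <- count_kmers_by_position(reads, k = 6)
  bg <- background_from_reference(genome, k = 6, both_strands = TRUE)
  tests <- test_positional_kmers(pk, bg, positions = "start")
  hit <- tests[tests$kmer == "ACGTAC", ]
  expect_lt(hit$log10_pvalue, -6)
  expect_equal(hit$direction, "over")
})

test_that("central observations are never extreme and zero-prob k-mers get a floor", {
  pk <- count_kmers_by_position(qc_reads(rep(c("AC", "AG", "CC", "GT"), 25)),
                                k = 2)
  bg <- background_from_reads(pk)
  tests <- test_positional_kmers(pk, bg, positions = "start")
  central <- tests[tests$observed == floor(tests$expected), ]
  expect_true(all(central$log10_pvalue > -1))

  ref_bg <- background_from_reference("ACACACAC", k = 2)
  tests2 <- test_positional_kmers(pk, ref_bg, positions = "start")
  novel <- tests2[tests2$kmer == "GT", ]   # absent from the reference
  expect_equal(novel$p, 1 / (2 * attr(ref_bg, "n_sites")))
  expect_true(is.finite(novel$log10_pvalue))

  bad <- count_kmers_by_position(qc_reads("ACGT"), k = 3)
  expect_error(test_positional_kmers(bad, bg), "k mismatch")
})

test_that("polynomial trend fits recover exact and degenerate cases", {
  pos <- 1:20
  counts <- 2 * pos^3 - pos + 5
  reads_tbl <- fake_positional_kmers(pos, counts, kmer = "AAAAAA", k = 6)
  # an exact polynomial fixture legitimately triggers lm's perfect-fit warning
  fit <- suppressWarnings(position_trend_fit(reads_tbl, "AAAAAA", degree = 3))
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_false(fit$degenerate)

  const <- fake_positional_kmers(pos, rep(7, 20), kmer = "AAAAAA", k = 6)
  dfit <- position_trend_fit(const, "AAAAAA", degree = 3)
  expect_true(dfit$degenerate)
  expect_equal(dfit$r2, 0)
  expect_equal(dfit$pvalue, 1)
})

test_that("noisy linear fits agree with a normal-equations oracle", {
  withr::with_seed(99, {
    x <- 1:40
    y <- round(10 * x + rnorm(40, sd = 5))
  })
  tbl <- fake_positional_kmers(x, y, kmer = "ACG", k = 3)
  fit <- position_trend_fit(tbl, "ACG", degree = 1)
  oracle <- ols_oracle(x, y, 1)
  expect_equal(fit$r2, oracle$r2, tolerance = 1e-9)
  expect_equal(fit$pvalue, oracle$pvalue, tolerance = 1e-9)
  expect_equal(fit$coefficients, oracle$coefficients, tolerance = 1e-6)

  g <- glance(fit)
  expect_equal(g$degree, 1L)
  expect_equal(nrow(tidy(fit)), 2L)
})

test_that("auto degree selection prefers the better adjusted fit", {
  pos <- 1:30
  cubic <- round(0.5 * pos^3 - 3 * pos^2 + 10)
  tbl <- fake_positional_kmers(pos, cubic, kmer = "GGG", k = 3)
  fit <- position_trend_fit(tbl, "GGG", degree = "auto")
  expect_equal(fit$degree, 3L)
})
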