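test_that("generated genomes respect length, composition and determinism", {
  g <- generate_genome(1000, gc = 0.5, seed = 61)
  expect_equal(nchar(g$seq), 1000L)
  gc_frac <- mean(strsplit(g$seq, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc_frac - 0.5), 4 * sqrt(0.25 / 1000))

  at_only <- generate_genome(500, gc = 0, seed = 62)
  expect_false(grepl("[GC]", at_only$seq))

  expect_identical(generate_genome(100, seed = 63)$seq,
                   generate_genome(100, seed = 63)$seq)
  expect_error(generate_genome(0), "length")
  expect_error(generate_genome(10, gc = 2), "gc")
})

test_that("an empty bias spec reproduces pure uniform sampling", {
  genome <- generate_genome(5000, seed = 64)
  reads <- generate_reads(genome, 300, 20, seed = 65)
  haystack <- paste0(genome$seq, "#", as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(genome$seq))))
  expect_true(all(vapply(reads$seq, grepl, logical(1), x = haystack,
                         fixed = TRUE)))
})

test_that("the injected start-motif fraction is recovered empirically", {
  genome <- generate_genome(50000, seed = 66)
  reads <- generate_reads(genome, 50000, 20,
                          bias = bias_spec(start_motif = list(motif = "ACGTAC",
                                                              fraction = 0.05)),
                          seed = 67)
  emp <- mean(startsWith(reads$seq, "ACGTAC"))
  background <- 4^-6
  expect_lt(abs(emp - (0.05 + (1 - 0.05) * background)),
            4 * sqrt(0.05 * 0.95 / 50000))
})

test_that("poly-run conversion strictly raises pure-run counts in the tail", {
  genome <- generate_genome(30000, seed = 68)
  mk <- function(prob) {
    generate_reads(genome, 10000, 20,
                   bias = bias_spec(polyrun_error = list(base = "G",
                                                         tail_length = 5,
                                                         conversion_prob = prob)),
                   seed = 69)
  }
  count_tail_runs <- function(reads) {
    pk <- count_kmers_by_position(reads, k = 6)
    tail <- pk[pk$position > 10 & pk$kmer == "GGGGGG", ]
    sum(tail$count)
  }
  expect_gt(count_tail_runs(mk(1)), count_tail_runs(mk(0)))
})

test_that("position enrichment raises the k-mer's frequency about fold-fold", {
  genome <- generate_genome(30000, seed = 70)
  plain <- generate_reads(genome, 20000, 15, seed = 71)
  rich <- generate_reads(genome, 20000, 15,
                         bias = bias_spec(position_enrichment = list(
                           kmer = "ACG", position = 5, fold = 4)),
                         seed = 71)
  f0 <- mean(substr(plain$seq, 5, 7) == "ACG")
  f1 <- mean(substr(rich$seq, 5, 7) == "ACG")
  expect_gt(f1 / f0, 3)
  expect_lt(f1 / f0, 5)
})

test_that("error gradients interpolate linearly along the read", {
  genome <- generate_genome(20000, seed = 72)
  clean <- generate_reads(genome, 20000, 11, seed = 73)
  noisy <- generate_reads(genome, 20000, 11,
                          bias = bias_spec(error_gradient = list(
                            start_rate = 0, end_rate = 0.2)),
                          seed = 73)
  rate_at <- function(j) mean(substr(noisy$seq, j, j) != substr(clean$seq, j, j))
  expect_equal(rate_at(1), 0)
  expect_lt(abs(rate_at(6) - 0.1), 4 * sqrt(0.1 * 0.9 / 20000))
  expect_lt(abs(rate_at(11) - 0.2), 4 * sqrt(0.2 * 0.8 / 20000))
})

test_that("bias specifications validate their fields", {
  expect_error(bias_spec(start_motif = list(motif = "ACG")), "missing bias fields")
  expect_error(bias_spec(start_motif = list(motif = "ACG", fraction = 2)),
               "\\[0, 1\\]")
  expect_error(bias_spec(position_enrichment = list(kmer = "A", position = 1,
                                                    fold = -1)), "fold")
  expect_error(generate_reads(generate_genome(100, seed = 1), 10, 5,
                              bias = bias_spec(start_motif = list(
                                motif = "ACGTAC", fraction = 0.1))),
               "longer than")
})

test_that("synthetic sets round-trip through FASTA/FASTQ with a JSON sidecar", {
  dir <- withr::local_tempdir()
  paths <- write_synthetic_set(dir, genome_length = 2000, n = 50,
                               read_length = 20, seed = 5)
  genome <- read_fasta(paths$genome)
  reads <- read_fastq(paths$reads)
  expect_equal(genome$length, 2000L)
  expect_equal(nrow(reads), 50L)
  sidecar <- jsonlite::read_json(paths$sidecar)
  expect_equal(sidecar$seed, 5L)
  expect_equal(sidecar$n, 50L)
})
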