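#' Generate a random reference genome
#'
#' I.i.d. bases with `P(G) = P(C) = gc/2` and `P(A) = P(T) = (1-gc)/2`.
#'
#' @param length Genome length (`>= 1`).
#' @param gc GC fraction in `[0, 1]` (default 0.5).
#' @param seed Optional integer seed.
#' @return A one-row `qc_reference` tibble.
#' @export
#' @examples
#' generate_genome(100, gc = 0.4, seed = 1)
generate_genome <- function(length, gc = 0.5, seed = NULL) {
  length <- as.integer(length)
  if (length < 1L) abort("length must be >= 1")
  if (gc < 0 || gc > 1) abort("gc must lie in [0, 1]")
  with_rng(seed, {
    bases <- sample(DNA_BASES, length, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    new_qc_reference(tibble(seq_id = "synthetic_genome",
                            seq = paste(bases, collapse = ""),
                            length = length))
  })
}

#' Specify biases to inject into generated reads
#'
#' Each component is optional; an empty spec produces error-free
#' uniform-sampling reads. Biases are applied post-sampling by overwriting
#' bases, so the genome composition stays clean and every injected effect
#' size is exactly computable.
#'
#' @param start_motif `list(motif =, fraction =)`: each read independently has
#'   its first `nchar(motif)` bases overwritten with probability `fraction`.
#' @param position_enrichment `list(kmer =, position =, fold =)`: the k-mer's
#'   frequency at the position is raised to about `fold` times its current
#'   level by overwriting a computed fraction of reads there.
#' @param polyrun_error `list(base =, tail_length =, conversion_prob =,
#'   run_length = 6)`: within the last `tail_length` window offsets, any
#'   window exactly one base away from a pure run of `base` is converted to
#'   the pure run with probability `conversion_prob` — the near-run-to-run
#'   error conversion seen as systematic poly-base artefacts at read ends.
#' @param error_gradient `list(start_rate =, end_rate =)`: per-position
#'   substitution rate linearly interpolated along the read.
#' @return An object of class `bias_spec`.
#' @export
bias_spec <- function(start_motif = NULL, position_enrichment = NULL,
                      polyrun_error = NULL, error_gradient = NULL) {
  chk <- function(x, fields, probs = character()) {
    if (is.null(x)) return(NULL)
    x <- as.list(x)
    missing <- setdiff(fields, names(x))
    if (length(missing)) abort(paste("missing bias fields:",
                                     paste(missing, collapse = ", ")))
    for (p in probs) {
      if (x[[p]] < 0 || x[[p]] > 1) abort(sprintf("%s must lie in [0, 1]", p))
    }
    x
  }
  pr <- chk(polyrun_error, c("base", "tail_length", "conversion_prob"),
            "conversion_prob")
  if (!is.null(pr)) pr$run_length <- pr$run_length %||% 6L
  pe <- chk(position_enrichment, c("kmer", "position", "fold"))
  if (!is.null(pe) && pe$fold <= 0) abort("fold must be > 0")
  structure(list(
    start_motif = chk(start_motif, c("motif", "fraction"), "fraction"),
    position_enrichment = pe,
    polyrun_error = pr,
    error_gradient = chk(error_gradient, c("start_rate", "end_rate"))
  ), class = "bias_spec")
}

is_empty_spec <- function(spec) all(vapply(spec, is.null, logical(1)))

#' Generate reads with known injected biases
#'
#' Samples reads under the uniform-sampling null (identical to
#' [simulate_reads()] with zero error) and then injects the biases described
#' by the [bias_spec()], in the order: error gradient, poly-run conversion,
#' position enrichment, start motif. With an empty spec every read is an
#' exact substring of the reference or its reverse complement.
#'
#' @param ref Reference: one-row `qc_reference` tibble or character string.
#' @param n Number of reads.
#' @param read_length Read length.
#' @param bias A [bias_spec()] (default: empty, i.e. unbiased).
#' @param seed Optional integer seed.
#' @return A `qc_reads` tibble.
#' @export
generate_reads <- function(ref, n, read_length, bias = bias_spec(), seed = NULL) {
  if (!inherits(bias, "bias_spec")) abort("bias must be a bias_spec()")
  ref_seq <- ref_sequence(ref)
  read_length <- as.integer(read_length)
  with_rng(seed, {
    sampled <- sample_read_seqs(ref_seq, n, read_length)
    seqs <- sampled$seqs
    err <- rep(0, read_length)
    if (!is.null(bias$error_gradient)) {
      err <- seq(bias$error_gradient$start_rate, bias$error_gradient$end_rate,
                 length.out = read_length)
      seqs <- apply_substitutions(seqs, err)
    }
    if (!is.null(bias$polyrun_error)) {
      seqs <- convert_polyruns(seqs, bias$polyrun_error, read_length)
    }
    if (!is.null(bias$position_enrichment)) {
      seqs <- enrich_position(seqs, bias$position_enrichment, read_length)
    }
    if (!is.null(bias$start_motif)) {
      motif <- toupper(bias$start_motif$motif)
      if (nchar(motif) > read_length) abort("start motif longer than the reads")
      sel <- stats::runif(n) < bias$start_motif$fraction
      substr(seqs[sel], 1L, nchar(motif)) <- motif
    }
    qual <- intToUtf8(error_to_phred(err) + 33L)
    qc_reads(seqs, read_id = provenance_ids("synth", sampled),
             qual = rep(qual, n), offset = 33L)
  })
}

# convert near-runs (Hamming distance 1 from a pure run) in the tail windows
# into pure runs with the stated probability
convert_polyruns <- function(seqs, pr, read_length) {
  k <- as.integer(pr$run_length)
  base <- toupper(pr$base)
  run <- strrep(base, k)
  last_start <- read_length - k + 1L
  starts <- seq.int(max(1L, last_start - as.integer(pr$tail_length) + 1L),
                    last_start)
  for (i in starts) {
    w <- substr(seqs, i, i + k - 1L)
    near <- nchar(gsub(base, "", w, fixed = TRUE)) == 1L
    conv <- near & stats::runif(length(seqs)) < pr$conversion_prob
    if (any(conv)) substr(seqs[conv], i, i + k - 1L) <- run
  }
  seqs
}

# overwrite enough reads at the position that the k-mer frequency becomes
# about `fold` times its current empirical level
enrich_position <- function(seqs, pe, read_length) {
  kmer <- toupper(pe$kmer)
  k <- nchar(kmer)
  i <- as.integer(pe$position)
  if (i + k - 1L > read_length) abort("enrichment window exceeds the reads")
  phat <- mean(substr(seqs, i, i + k - 1L) == kmer)
  frac <- min(1, max(0, (pe$fold - 1) * phat / (1 - phat)))
  sel <- stats::runif(length(seqs)) < frac
  substr(seqs[sel], i, i + k - 1L) <- kmer
  seqs
}

#' Write a synthetic genome and read set to disk
#'
#' Convenience wrapper for the command-line `synth` subcommand: writes the
#' reference as FASTA, the reads as FASTQ, and a JSON sidecar recording the
#' generation parameters and seed.
#'
#' @param dir Output directory (created if missing).
#' @param genome_length,gc Genome parameters for [generate_genome()].
#' @param n,read_length Read set parameters for [generate_reads()].
#' @param bias A [bias_spec()].
#' @param seed Integer seed (required, for the sidecar).
#' @return Invisibly, a list of the three paths written.
#' @export
write_synthetic_set <- function(dir, genome_length, n, read_length,
                                gc = 0.5, bias = bias_spec(), seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- generate_genome(genome_length, gc = gc, seed = seed)
  reads <- generate_reads(genome, n, read_length, bias = bias, seed = seed + 1L)
  fa <- file.path(dir, "genome.fa")
  writeLines(c(paste0(">", genome$seq_id), genome$seq), fa)
  fq <- file.path(dir, "reads.fastq")
  write_fastq(reads, fq)
  sidecar <- file.path(dir, "synth.json")
  jsonlite::write_json(
    list(genome_length = genome_length, gc = gc, n = n,
         read_length = read_length, seed = seed,
         bias = Filter(Negate(is.null), unclass(bias))),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(list(genome = fa, reads = fq, sidecar = sidecar))
}
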