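#' Configuration for a full QC run
#'
#' Bundles all settings of the combined workflow (filter, base calls, k-mer
#' tests, KL divergence, optional bootstrap) with validated defaults. Paths
#' are checked at construction time.
#'
#' @param fastq Path to the input FASTQ (plain or gzip).
#' @param out_dir Output directory; created on run.
#' @param offset Quality offset: `"auto"`, 33 or 64.
#' @param filter Apply the artefact filters before analysis.
#' @param primer Optional primer for the prefix filter.
#' @param max_mismatch Primer mismatch budget.
#' @param max_non_a Poly-A threshold (`NULL` = 5% default).
#' @param k K-mer length for the positional tests and the divergence analysis
#'   (default 6).
#' @param positions Positions for the k-mer tests (`"start"`, `"all"`, or an
#'   integer vector).
#' @param background `"reads"` (pooled read windows) or `"reference"`.
#' @param reference FASTA path, required when `background = "reference"` or
#'   `bootstrap = TRUE`.
#' @param alpha Smoothing pseudocount for the divergence analysis.
#' @param min_coverage Coverage floor for KL matrix positions.
#' @param bootstrap Run the simulator-based null calibration.
#' @param replicates Bootstrap replicates (default 100).
#' @param alpha_level Significance level for the headline bias flags, applied
#'   to Bonferroni-corrected p-values (default 0.01).
#' @param basecall_diff_threshold Absolute A-T / C-G fraction difference that
#'   flags base-call asymmetry (default 0.03).
#' @param kl_ratio_threshold First-position row/column mean over interior
#'   grand mean ratio that flags start-position divergence (default 2).
#' @param seed Integer seed used for every stochastic stage.
#' @return A validated list of class `qc_config`.
#' @export
qc_config <- function(fastq, out_dir, offset = "auto",
                      filter = TRUE, primer = NULL, max_mismatch = 1L,
                      max_non_a = NULL,
                      k = 6L, positions = "start",
                      background = c("reads", "reference"), reference = NULL,
                      alpha = 0.5, min_coverage = 1000,
                      bootstrap = FALSE, replicates = 100L,
                      alpha_level = 0.01, basecall_diff_threshold = 0.03,
                      kl_ratio_threshold = 2, seed = 1L) {
  background <- match.arg(background)
  if (!file.exists(fastq)) abort(sprintf("no such file: %s", fastq))
  if (background == "reference" || bootstrap) {
    if (is.null(reference)) abort("a reference FASTA is required for this configuration")
    if (!file.exists(reference)) abort(sprintf("no such file: %s", reference))
  }
  structure(list(fastq = fastq, out_dir = out_dir, offset = offset,
                 filter = filter, primer = primer,
                 max_mismatch = as.integer(max_mismatch),
                 max_non_a = max_non_a, k = as.integer(k),
                 positions = positions, background = background,
                 reference = reference, alpha = alpha,
                 min_coverage = min_coverage, bootstrap = bootstrap,
                 replicates = as.integer(replicates),
                 alpha_level = alpha_level,
                 basecall_diff_threshold = basecall_diff_threshold,
                 kl_ratio_threshold = kl_ratio_threshold,
                 seed = as.integer(seed)),
            class = "qc_config")
}

stage <- function(name, code) {
  t0 <- Sys.time()
  res <- tryCatch(force(code), error = function(e) {
    abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
  })
  inform(sprintf("[%s] done in %.1fs", name,
                 as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full QC report
#'
#' Executes the recommended three-stage workflow — artefact filtering, base
#' call profiling, positional k-mer testing, KL divergence analysis, and
#' (optionally) bootstrap calibration — and writes TSV tables plus a single
#' machine-readable JSON summary with headline bias flags. The exit status of
#' the CLI wrapper reflects execution success only, never the QC verdict, so
#' pipelines can distinguish a crash from "biased data". Outputs contain no
#' timestamps: rerunning with the same configuration and seed reproduces them
#' byte for byte.
#'
#' @param config A [qc_config()].
#' @return Invisibly, a list of class `qc_report` with all intermediate
#'   results and the summary.
#' @export
run_full_report <- function(config) {
  if (!inherits(config, "qc_config")) abort("config must be a qc_config()")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  reads <- stage("read", read_fastq(config$fastq, offset = config$offset))
  if (!nrow(reads)) abort("stage 'read' failed: empty read set")

  filt <- NULL
  if (config$filter) {
    filt <- stage("filter", filter_artefacts(reads, primer = config$primer,
                                             max_mismatch = config$max_mismatch,
                                             max_non_a = config$max_non_a))
    readr::write_tsv(filt$report, out("filter_report.tsv"))
    if (nrow(filt$removed)) write_fastq(filt$removed, out("removed_reads.fastq"))
    reads <- filt$kept
    if (!nrow(reads)) abort("stage 'filter' failed: no reads survived filtering")
  }

  bc <- stage("basecalls", {
    counts <- count_basecalls(reads)
    fr <- basecall_fractions(counts)
    tsv <- dplyr::left_join(counts, fr, by = c("position", "coverage"))
    readr::write_tsv(tsv, out("basecalls.tsv"))
    list(counts = counts, fractions = fr)
  })
  qp <- NULL
  if (!all(is.na(reads$qual))) {
    qp <- stage("quality", {
      q <- quality_profile(reads)
      readr::write_tsv(q, out("quality_profile.tsv"))
      q
    })
  }

  pk <- stage("kmers", count_kmers_by_position(reads, config$k))
  bg <- if (config$background == "reference") {
    background_from_reference(read_fasta(config$reference), config$k,
                              both_strands = TRUE)
  } else {
    background_from_reads(pk)
  }
  tests <- stage("kmer-tests", {
    tt <- test_positional_kmers(pk, bg, positions = config$positions)
    readr::write_tsv(tt, out("kmer_tests.tsv"))
    tt
  })

  klm <- stage("kldiv", {
    km <- kl_matrix(pk, alpha = config$alpha, min_coverage = config$min_coverage)
    readr::write_tsv(tidy(km), out("kl_matrix.tsv"))
    km
  })

  cal <- NULL; es <- NULL
  if (config$bootstrap) {
    cal <- stage("bootstrap", {
      prof <- if (is.null(qp)) rep(0, max(nchar(reads$seq)))
              else qp$mean_error_prob
      calibrate_null(read_fasta(config$reference), n = nrow(reads),
                     read_length = max(nchar(reads$seq)),
                     error_profile = prof, replicates = config$replicates,
                     k = config$k, alpha = config$alpha,
                     min_coverage = config$min_coverage, seed = config$seed)
    })
    es <- effect_sizes(klm, cal)
    readr::write_tsv(tidy(es), out("effect_sizes.tsv"))
  }

  summary <- report_summary(config, reads, filt, bc, tests, klm, es)
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(structure(list(config = config, filter = filt, basecalls = bc,
                           quality = qp, tests = tests, kl = klm,
                           calibration = cal, effect_sizes = es,
                           summary = summary),
                      class = "qc_report"))
}

report_summary <- function(config, reads, filt, bc, tests, klm, es) {
  sig <- tests$bonferroni_log10 < log10(config$alpha_level)
  top <- utils::head(tests[order(tests$log10_pvalue), ], 10)
  v <- klm$values
  first <- c(v[1, -1], v[-1, 1])
  interior <- v[-1, -1]
  kl_ratio <- mean(first) / offdiag_mean(interior)
  max_diff <- max(abs(bc$fractions$diff_AT), abs(bc$fractions$diff_CG))
  flags <- list(
    start_kmer_bias = any(sig),
    basecall_asymmetry = max_diff > config$basecall_diff_threshold,
    first_position_divergence = kl_ratio > config$kl_ratio_threshold
  )
  summary <- list(
    n_reads = nrow(reads),
    seed = config$seed,
    flags = flags,
    bias_detected = any(unlist(flags)),
    n_kmer_tests = nrow(tests),
    n_significant_bonferroni = sum(sig),
    max_basecall_diff = max_diff,
    kl_first_position_ratio = kl_ratio,
    top_kmers = top[c("kmer", "position", "observed", "expected",
                      "log10_pvalue", "direction")]
  )
  if (!is.null(filt)) summary$filter <- as.list(filt$report)
  if (!is.null(es)) {
    g <- glance(es)
    summary$bootstrap <- list(max_abs_z = g$max_abs_z,
                              argmax_cell = c(g$argmax_from, g$argmax_to),
                              prop_abs_z_lt_4 = g$prop_abs_z_lt_4)
    summary$flags$divergence_effect <- g$max_abs_z > 4
    summary$bias_detected <- any(unlist(summary$flags))
  }
  summary
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report for %s: %d reads analysed\n",
              x$config$fastq, x$summary$n_reads))
  for (f in names(x$summary$flags)) {
    cat(sprintf("  %-28s %s\n", f, if (isTRUE(x$summary$flags[[f]])) "FLAGGED" else "ok"))
  }
  invisible(x)
}
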