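#' Per-position base-call counts
#'
#' Counts how many times each of the five base symbols (A, C, G, T, N) was
#' called at every position across a read set. Variable read lengths are
#' supported: a position's `coverage` is the number of reads long enough to
#' cover it, and counts across the five symbols always sum to that coverage.
#'
#' @param reads A `qc_reads` tibble with at least one read.
#' @return A tibble of class `basecall_counts`: one row per position (1-based)
#'   with columns `position`, `A`, `C`, `G`, `T`, `N`, `coverage`.
#' @export
#' @examples
#' count_basecalls(qc_reads(c("AC", "AG")))
count_basecalls <- function(reads) {
  if (!nrow(reads)) abort("empty read set")
  seqs <- reads$seq
  max_l <- max(nchar(seqs))
  rows <- vector("list", max_l)
  for (i in seq_len(max_l)) {
    ch <- substr(seqs, i, i)
    ch <- ch[ch != ""]
    tab <- table(factor(ch, levels = BASE_SYMBOLS))
    rows[[i]] <- c(position = i, as.integer(tab), coverage = length(ch))
  }
  m <- do.call(rbind, rows)
  colnames(m) <- c("position", BASE_SYMBOLS, "coverage")
  structure(as_tibble(m), class = c("basecall_counts", class(as_tibble(m))))
}

#' Per-position base-call fractions and strand-symmetry diagnostics
#'
#' Normalises a [count_basecalls()] table to fractions and adds the A\eqn{-}T
#' and C\eqn{-}G per-position differences. In unbiased whole-genome data the
#' two members of each complementary couple should be called equally often, so
#' both differences should sit near zero at every position.
#'
#' @param counts A `basecall_counts` tibble.
#' @return A tibble with `position`, `coverage`, `frac_A` ... `frac_N`,
#'   `diff_AT` (= frac_A - frac_T) and `diff_CG` (= frac_C - frac_G).
#' @export
basecall_fractions <- function(counts) {
  counts <- dplyr::filter(counts, .data$coverage > 0L)
  fr <- lapply(BASE_SYMBOLS, function(b) counts[[b]] / counts$coverage)
  names(fr) <- paste0("frac_", BASE_SYMBOLS)
  out <- dplyr::bind_cols(counts[c("position", "coverage")], as_tibble(fr))
  dplyr::mutate(out,
                diff_AT = .data$frac_A - .data$frac_T,
                diff_CG = .data$frac_C - .data$frac_G)
}

#' Per-position mean quality profile
#'
#' Computes the arithmetic mean Phred score at each read position, together
#' with the mean error probability. The latter averages the per-base
#' probabilities \eqn{10^{-Q/10}} directly (not \eqn{10^{-\bar Q/10}}), so it
#' is an unbiased per-position error rate suitable for training the read
#' simulator.
#'
#' @param reads A `qc_reads` tibble whose `qual` column is populated.
#' @return A tibble of class `quality_profile` with `position`, `n`, `mean_q`,
#'   `mean_error_prob`.
#' @export
quality_profile <- function(reads) {
  if (!nrow(reads)) abort("empty read set")
  if (all(is.na(reads$qual))) abort("read set has no quality strings")
  offset <- attr(reads, "offset") %||% 33L
  qs <- reads$qual[!is.na(reads$qual)]
  max_l <- max(nchar(qs))
  rows <- vector("list", max_l)
  for (i in seq_len(max_l)) {
    ch <- substr(qs, i, i)
    ch <- ch[ch != ""]
    q <- utf8ToInt(paste(ch, collapse = "")) - offset
    rows[[i]] <- tibble(position = i, n = length(q),
                        mean_q = mean(q),
                        mean_error_prob = mean(10^(-q / 10)))
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("quality_profile", class(out)))
}
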