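#' Count k-mers at every read start-offset
#'
#' Tallies, for each position `i` and each k-mer `w` over \{A,C,G,T\}, the
#' number of reads whose window `[i, i+k-1]` equals `w`. Windows containing an
#' `N` are excluded from the counts and tallied per position in `skipped`;
#' `n_windows[i]` is the number of reads long enough to provide a window at
#' `i`, so `sum(counts at i) + skipped[i] == n_windows[i]` always holds. With
#' `k = 1` this reduces exactly to the per-position base-call counts for the
#' four unambiguous bases.
#'
#' @param reads A `qc_reads` tibble.
#' @param k Window length, `1 <= k <=` the maximum read length.
#' @return A tibble of class `positional_kmers` in long form (`position`,
#'   `kmer`, `count`; zero counts omitted) with attributes `k` and `windows`
#'   (a tibble of `position`, `n_windows`, `skipped`).
#' @export
#' @examples
#' count_kmers_by_position(qc_reads("ACGT"), k = 2)
count_kmers_by_position <- function(reads, k) {
  k <- as.integer(k)
  if (!nrow(reads)) abort("empty read set")
  if (k < 1L) abort("k must be >= 1")
  max_l <- max(nchar(reads$seq))
  if (k > max_l) abort(sprintf("k = %d exceeds every read length (max %d)", k, max_l))
  seqs <- reads$seq
  n_pos <- max_l - k + 1L
  counts <- vector("list", n_pos)
  n_windows <- integer(n_pos)
  skipped <- integer(n_pos)
  for (i in seq_len(n_pos)) {
    w <- substr(seqs, i, i + k - 1L)
    w <- w[nchar(w) == k]
    n_windows[i] <- length(w)
    has_n <- grepl("N", w, fixed = TRUE)
    skipped[i] <- sum(has_n)
    tab <- table(w[!has_n])
    counts[[i]] <- tibble(position = i,
                          kmer = names(tab),
                          count = as.integer(tab))
  }
  out <- dplyr::bind_rows(counts)
  structure(out,
            k = k,
            windows = tibble(position = seq_len(n_pos),
                             n_windows = n_windows, skipped = skipped),
            class = c("positional_kmers", class(out)))
}

#' Per-position window bookkeeping of a positional k-mer table
#'
#' @param table A `positional_kmers` tibble.
#' @return Tibble with `position`, `n_windows`, `skipped` and `n_valid`
#'   (= `n_windows - skipped`, the binomial denominator at that position).
#' @export
window_counts <- function(table) {
  w <- attr(table, "windows")
  if (is.null(w)) abort("not a positional_kmers table")
  dplyr::mutate(w, n_valid = .data$n_windows - .data$skipped)
}

#' Background k-mer model from a reference sequence
#'
#' Slides a window of length `k` along the reference (skipping windows that
#' contain `N`) and, optionally, along its reverse complement, and converts
#' occurrence counts `m_w` into probabilities `p_w = m_w / n_sites` where
#' `n_sites` is the total number of valid windows counted. Under the uniform
#' sampling hypothesis every read has probability `p_w` of carrying `w` at any
#' given offset, which is the expectation the positional tests are run
#' against. Reads sample both strands, so `both_strands = TRUE` is the
#' appropriate background for real or simulated read pools.
#'
#' @param ref Reference: a one-row `qc_reference` tibble or a character string.
#' @param k Window length.
#' @param both_strands Also count reverse-complement windows.
#' @return A tibble of class `kmer_background` (`kmer`, `occurrences`, `prob`)
#'   with attributes `k`, `source = "reference"`, `n_sites`.
#' @export
background_from_reference <- function(ref, k, both_strands = FALSE) {
  k <- as.integer(k)
  seq <- ref_sequence(ref)
  if (nchar(seq) < k) abort("reference shorter than k")
  count_windows <- function(s) {
    g <- nchar(s)
    w <- substring(s, seq_len(g - k + 1L), k:g)
    w[!grepl("N", w, fixed = TRUE)]
  }
  w <- count_windows(seq)
  if (both_strands) w <- c(w, count_windows(revcomp(seq)))
  if (!length(w)) abort("no valid windows in reference")
  tab <- table(w)
  out <- tibble(kmer = names(tab),
                occurrences = as.integer(tab),
                prob = as.integer(tab) / length(w))
  structure(out, k = k, source = "reference", n_sites = length(w),
            class = c("kmer_background", class(out)))
}

#' Background k-mer model from the read pool itself
#'
#' When no reference is available the pooled window counts of the reads,
#' summed over all positions, serve as the background distribution.
#'
#' @param table A `positional_kmers` tibble.
#' @return A `kmer_background` tibble with `source = "read_pool"`.
#' @export
background_from_reads <- function(table) {
  if (!nrow(table)) abort("empty positional k-mer table")
  pooled <- table %>%
    dplyr::group_by(.data$kmer) %>%
    dplyr::summarise(occurrences = sum(.data$count), .groups = "drop")
  n_sites <- sum(pooled$occurrences)
  if (n_sites == 0L) abort("all-zero positional k-mer table")
  out <- dplyr::mutate(pooled, prob = .data$occurrences / n_sites)
  structure(out, k = attr(table, "k"), source = "read_pool", n_sites = n_sites,
            class = c("kmer_background", class(out)))
}

#' Test positional k-mer counts against a background model
#'
#' For each requested position and each k-mer with background support or a
#' non-zero observation, computes the one-sided binomial tail p-value of the
#' observed count against Binomial(`n_valid`, `p_w`) — the uniform-sampling
#' null. Background k-mers with probability zero that are nevertheless
#' observed get `p` floored at `1 / (2 n_sites)`, a conservative stand-in that
#' avoids log(0) while still reporting them as the extreme observations they
#' are. Bonferroni correction runs over all (k-mer, position) tests performed.
#'
#' @param table A `positional_kmers` tibble.
#' @param bg A `kmer_background` with the same `k`.
#' @param positions `"start"` (position 1), `"all"`, or an integer vector.
#' @return Tibble of class `kmer_tests`, sorted by `log10_pvalue`: `kmer`,
#'   `position`, `observed`, `n`, `p`, `expected`, `log10_pvalue`,
#'   `direction`, `bonferroni_log10`.
#' @export
test_positional_kmers <- function(table, bg, positions = "start") {
  k <- attr(table, "k")
  if (!identical(k, attr(bg, "k"))) {
    abort(sprintf("k mismatch: table has k = %s, background k = %s",
                  k, attr(bg, "k")))
  }
  wc <- window_counts(table)
  pos <- if (identical(positions, "start")) 1L
         else if (identical(positions, "all")) wc$position[wc$n_valid > 0L]
         else as.integer(positions)
  if (!all(pos %in% wc$position)) abort("requested positions outside the table")
  n_sites <- attr(bg, "n_sites")
  floor_p <- 1 / (2 * n_sites)
  bg_kmers <- bg$kmer[bg$prob > 0]
  per_pos <- lapply(pos, function(i) {
    obs <- dplyr::filter(table, .data$position == i)
    kmers <- union(bg_kmers, obs$kmer)
    count <- obs$count[match(kmers, obs$kmer)] %+na% 0L
    p <- bg$prob[match(kmers, bg$kmer)] %+na% 0
    p[p == 0] <- floor_p
    n <- wc$n_valid[wc$position == i]
    dplyr::bind_cols(tibble(kmer = kmers, position = i),
                     binomial_log10_pvalue(count, n, p)[-1:-3],
                     tibble(n = n, p = p, observed = count))
  })
  out <- dplyr::bind_rows(per_pos)
  n_tests <- nrow(out)
  out <- out %>%
    dplyr::mutate(bonferroni_log10 = pmin(0, .data$log10_pvalue + log10(n_tests))) %>%
    dplyr::select("kmer", "position", "observed", "n", "p", "expected",
                  "log10_pvalue", "direction", "bonferroni_log10") %>%
    dplyr::arrange(.data$log10_pvalue)
  structure(out, k = k, n_tests = n_tests,
            class = c("kmer_tests", class(out)))
}

#' Fit a polynomial trend of k-mer count against read position
#'
#' Ordinary least squares of the per-position counts of one k-mer on position,
#' at degree 1 (linear) or 3 (cubic); `degree = "auto"` fits both and keeps
#' the better adjusted R-squared. Artefactual k-mers — poly-runs created by
#' systematic error conversion, for instance — show strong positional trends,
#' while under position independence counts are flat and the fit is null.
#'
#' @param table A `positional_kmers` tibble.
#' @param kmer The k-mer to fit.
#' @param degree 1, 3, or `"auto"`.
#' @return An object of class `trend_fit`; see [tidy()] and [glance()]
#'   methods. Constant counts are flagged `degenerate` with `r2 = 0`,
#'   `pvalue = 1`.
#' @export
position_trend_fit <- function(table, kmer, degree = "auto") {
  wc <- window_counts(table)
  usable <- wc$position[wc$n_valid > 0L]
  obs <- dplyr::filter(table, .data$kmer == !!kmer)
  dat <- tibble(position = usable,
                count = obs$count[match(usable, obs$position)] %+na% 0L)
  degs <- if (identical(degree, "auto")) c(1L, 3L) else as.integer(degree)
  if (!all(degs %in% c(1L, 3L))) abort("degree must be 1, 3 or \"auto\"")
  if (nrow(dat) < max(degs) + 2L) abort("too few positions for the requested degree")

  if (stats::var(dat$count) == 0) {
    return(structure(list(kmer = kmer, degree = degs[1], fit = NULL, data = dat,
                          r2 = 0, adj_r2 = 0, pvalue = 1, degenerate = TRUE,
                          coefficients = c(dat$count[1], rep(0, degs[1]))),
                     class = "trend_fit"))
  }
  fits <- lapply(degs, function(d) {
    stats::lm(count ~ poly(position, degree = d, raw = TRUE), data = dat)
  })
  adj <- vapply(fits, function(f) summary(f)$adj.r.squared, numeric(1))
  best <- which.max(adj)
  fit <- fits[[best]]
  sm <- summary(fit)
  fs <- sm$fstatistic
  structure(list(kmer = kmer, degree = degs[best], fit = fit, data = dat,
                 r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
                 pvalue = unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)),
                 degenerate = FALSE,
                 coefficients = unname(stats::coef(fit))),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("Positional trend fit for %s: degree %d, r2 = %.4f, p = %.3g%s\n",
              x$kmer, x$degree, x$r2, x$pvalue,
              if (x$degenerate) " (degenerate: constant counts)" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname position_trend_fit
#' @param x A `trend_fit` object.
#' @param ... Unused.
#' @method tidy trend_fit
#' @export
tidy.trend_fit <- function(x, ...) {
  tibble(term = paste0("position^", seq_along(x$coefficients) - 1L),
         estimate = x$coefficients)
}

#' @rdname position_trend_fit
#' @method glance trend_fit
#' @export
glance.trend_fit <- function(x, ...) {
  tibble(kmer = x$kmer, degree = x$degree, r2 = x$r2, adj_r2 = x$adj_r2,
         pvalue = x$pvalue, degenerate = x$degenerate,
         n_positions = nrow(x$data))
}
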