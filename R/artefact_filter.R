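new_filter_result <- function(kept, removed, report) {
  structure(list(kept = kept, removed = removed, report = report),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' Remove poly-A fragments
#'
#' A read is removed when its number of non-A bases is at most `max_non_a`.
#' Poly-A fragments arise as reflection artefacts at the periphery of flow
#' cells and distort base-call and k-mer statistics if left in. The default
#' threshold allows 5% non-A bases (`floor(0.05 * length)`, per read), which
#' removes the artefact without touching genuinely A-rich genomic reads.
#'
#' @param reads A `qc_reads` tibble.
#' @param max_non_a Maximum number of non-A bases for removal; `NULL` for the
#'   5% default.
#' @return A `filter_result`: list with `kept` and `removed` read sets and a
#'   one-row `report` tibble.
#' @export
filter_polya <- function(reads, max_non_a = NULL) {
  lens <- nchar(reads$seq)
  non_a <- nchar(gsub("A", "", reads$seq, fixed = TRUE))
  thr <- if (is.null(max_non_a)) floor(0.05 * lens) else rep_len(max_non_a, length(lens))
  drop <- non_a <= thr
  offset <- attr(reads, "offset")
  new_filter_result(
    kept = new_qc_reads(reads[!drop, ], offset),
    removed = new_qc_reads(reads[drop, ], offset),
    report = tibble(filter = "polyA", n_input = nrow(reads),
                    n_kept = sum(!drop), n_removed = sum(drop)))
}

# mismatches of each read's prefix against `primer`, counted over the
# available prefix length (N counts as a mismatch)
prefix_mismatches <- function(seq, primer) {
  plen <- nchar(primer)
  avail <- pmin(nchar(seq), plen)
  mism <- integer(length(seq))
  for (i in seq_len(plen)) {
    at <- avail >= i
    mism[at] <- mism[at] + (substr(seq[at], i, i) != substr(primer, i, i))
  }
  list(mismatches = mism, available = avail)
}

#' Remove reads carrying a primer/adapter prefix
#'
#' A read is removed when its first `nchar(primer)` bases match the primer
#' with at most `max_mismatch` mismatches (an `N` counts as a mismatch).
#' Reads shorter than the primer are compared over the available prefix with
#' a proportionally scaled mismatch budget.
#'
#' @param reads A `qc_reads` tibble.
#' @param primer Primer sequence over \{A,C,G,T\}, non-empty.
#' @param max_mismatch Mismatch budget over the full primer length (default 1).
#' @return A `filter_result`.
#' @export
filter_primer_prefix <- function(reads, primer, max_mismatch = 1L) {
  primer <- toupper(primer)
  if (!nchar(primer) || grepl("[^ACGT]", primer)) {
    abort("primer must be a non-empty string over A, C, G, T")
  }
  pm <- prefix_mismatches(reads$seq, primer)
  budget <- floor(max_mismatch * pm$available / nchar(primer))
  drop <- pm$mismatches <= budget
  offset <- attr(reads, "offset")
  new_filter_result(
    kept = new_qc_reads(reads[!drop, ], offset),
    removed = new_qc_reads(reads[drop, ], offset),
    report = tibble(filter = "primer", n_input = nrow(reads),
                    n_kept = sum(!drop), n_removed = sum(drop),
                    primer = primer))
}

#' Combined artefact filtering
#'
#' Applies the poly-A filter and then, on the survivors, the primer-prefix
#' filter. Removed reads are returned (tagged with the removing filter), never
#' silently discarded, so the filtering is fully auditable: the report always
#' satisfies `n_input == n_kept + n_removed_polyA + n_removed_primer`.
#'
#' @inheritParams filter_polya
#' @inheritParams filter_primer_prefix
#' @param primer Optional primer; `NULL` skips the primer filter.
#' @return A `filter_result` whose `removed` set has a `reason` column and
#'   whose report carries both removal counts.
#' @export
filter_artefacts <- function(reads, primer = NULL, max_mismatch = 1L,
                             max_non_a = NULL) {
  pa <- filter_polya(reads, max_non_a = max_non_a)
  removed <- dplyr::mutate(pa$removed, reason = "polyA")
  kept <- pa$kept
  n_primer <- 0L
  if (!is.null(primer)) {
    pr <- filter_primer_prefix(kept, primer, max_mismatch = max_mismatch)
    removed <- dplyr::bind_rows(removed,
                                dplyr::mutate(pr$removed, reason = "primer"))
    kept <- pr$kept
    n_primer <- pr$report$n_removed
  }
  new_filter_result(
    kept = kept,
    removed = new_qc_reads(removed, attr(reads, "offset")),
    report = tibble(n_input = nrow(reads), n_kept = nrow(kept),
                    n_removed_polyA = pa$report$n_removed,
                    n_removed_primer = n_primer,
                    primer = primer %||% NA_character_))
}
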