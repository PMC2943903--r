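#' Smoothed k-mer distribution at one read position
#'
#' Converts the window counts at position `i` into a probability distribution
#' over all `4^k` k-mers with additive (pseudocount) smoothing:
#' `prob(w) = (count(w) + alpha) / (n_valid + alpha * 4^k)`. With `alpha > 0`
#' every k-mer has positive probability, which is what makes pairwise KL
#' divergences finite; `alpha = 0` keeps the raw empirical distribution.
#'
#' @param table A `positional_kmers` tibble.
#' @param i Read position (1-based window start).
#' @param alpha Pseudocount, `>= 0` (default 0.5).
#' @return A tibble of class `position_distribution` (`kmer`, `count`, `prob`
#'   over all `4^k` k-mers) with attributes `position`, `k`, `alpha`,
#'   `n_valid`.
#' @export
position_distribution <- function(table, i, alpha = 0.5) {
  k <- attr(table, "k")
  if (alpha < 0) abort("alpha must be >= 0")
  wc <- window_counts(table)
  if (!i %in% wc$position) abort(sprintf("no position %s in table", i))
  n_valid <- wc$n_valid[wc$position == i]
  if (n_valid == 0L) abort(sprintf("no valid windows at position %d", i))
  kmers <- all_kmers(k)
  obs <- dplyr::filter(table, .data$position == !!i)
  count <- obs$count[match(kmers, obs$kmer)] %+na% 0L
  out <- tibble(kmer = kmers, count = count,
                prob = (count + alpha) / (n_valid + alpha * 4^k))
  structure(out, position = as.integer(i), k = k, alpha = alpha,
            n_valid = n_valid,
            class = c("position_distribution", class(out)))
}

#' Kullback-Leibler divergence between two k-mer distributions
#'
#' \eqn{KL(P\|Q) = \sum_w P(w) \log_2(P(w)/Q(w))}, in bits: the average number
#' of bits wasted per symbol when encoding with `Q` while symbols are really
#' distributed as `P`. Terms with `P(w) = 0` contribute nothing; a k-mer with
#' `P(w) > 0` but `Q(w) = 0` makes the divergence undefined and raises an
#' error (smooth with `alpha > 0` to guarantee shared support). KL is
#' asymmetric and non-negative.
#'
#' @param p,q `position_distribution` tibbles with the same `k`, or bare
#'   numeric probability vectors of equal length.
#' @return Divergence in bits (`>= 0`).
#' @export
#' @examples
#' kl_divergence(c(0.5, 0.5), c(0.25, 0.75))
kl_divergence <- function(p, q) {
  if (is.data.frame(p)) {
    if (!identical(attr(p, "k"), attr(q, "k"))) abort("distributions differ in k")
    q <- q$prob[match(p$kmer, q$kmer)]
    p <- p$prob
  }
  if (length(p) != length(q)) abort("distributions differ in support size")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    abort("probabilities must sum to 1")
  }
  on <- p > 0
  if (any(q[on] == 0)) abort("unsmoothed zero in Q where P > 0")
  sum(p[on] * log2(p[on] / q[on]))
}

#' Pairwise KL divergence matrix over read positions
#'
#' Computes the smoothed k-mer distribution at every usable position and the
#' KL divergence for every ordered pair, `values[i, j] = KL(P_i || P_j)`.
#' Positions with fewer than `min_coverage` valid windows are dropped (and
#' recorded), mirroring the usual trimming of noise-dominated final cycles.
#' The matrix has an exactly zero diagonal and is not symmetric.
#'
#' @param table A `positional_kmers` tibble.
#' @param alpha Smoothing pseudocount (default 0.5).
#' @param min_coverage Minimum valid windows for a position to enter the
#'   matrix (default 1000).
#' @return An object of class `kl_matrix`: list with `values` (named matrix,
#'   bits), `positions`, `dropped`, `k`, `alpha`.
#' @export
kl_matrix <- function(table, alpha = 0.5, min_coverage = 1000) {
  k <- attr(table, "k")
  wc <- window_counts(table)
  keep <- wc$position[wc$n_valid >= max(min_coverage, 1)]
  dropped <- setdiff(wc$position, keep)
  if (length(keep) < 2L) abort("fewer than 2 positions with sufficient coverage")
  dists <- lapply(keep, function(i) position_distribution(table, i, alpha)$prob)
  P <- do.call(rbind, dists)                 # n_pos x 4^k
  if (any(P == 0)) {
    abort("zero probabilities in smoothed distributions; increase alpha")
  }
  S <- P %*% t(log2(P))                      # S[i, j] = sum_w P_i(w) log2 P_j(w)
  values <- matrix(diag(S), nrow(S), ncol(S)) - S
  values[values < 0 & values > -1e-9] <- 0   # clamp float dust; Gibbs says >= 0
  dimnames(values) <- list(keep, keep)
  structure(list(values = values, positions = keep, dropped = dropped,
                 k = k, alpha = alpha),
            class = "kl_matrix")
}

#' @export
print.kl_matrix <- function(x, ...) {
  v <- x$values[upper.tri(x$values) | lower.tri(x$values)]
  cat(sprintf("KL divergence matrix: k = %d, %d positions, alpha = %g\n",
              x$k, length(x$positions), x$alpha))
  cat(sprintf("off-diagonal mean %.4g bits, max %.4g bits\n", mean(v), max(v)))
  invisible(x)
}

#' @rdname kl_matrix
#' @param x A `kl_matrix` object.
#' @param ... Unused.
#' @method tidy kl_matrix
#' @export
tidy.kl_matrix <- function(x, ...) {
  long <- as_tibble(as.data.frame.table(x$values, stringsAsFactors = FALSE))
  names(long) <- c("from", "to", "kl")
  dplyr::mutate(long, from = as.integer(.data$from), to = as.integer(.data$to))
}

# Mean of the off-diagonal cells of a square matrix.
offdiag_mean <- function(m) mean(m[row(m) != col(m)])
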