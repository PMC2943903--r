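#' Stirling-series log-factorial
#'
#' \eqn{\ln n! \approx n\ln n - n + \tfrac12\ln(2\pi n) + 1/(12n)}. The
#' \eqn{1/(12n)} term keeps the residual at \eqn{\sim 1/(360 n^3)}, far inside
#' the \eqn{1/(12n)} envelope of the two-term series, which matters because
#' tail probabilities anchor an entire log-space summation on one factorial
#' evaluation.
#'
#' @param n Numeric vector, `n >= 1`.
#' @return `log(n!)` (natural log).
#' @export
#' @examples
#' stirling_log_factorial(10) - sum(log(1:10))
stirling_log_factorial <- function(n) {
  if (any(n < 1)) abort("stirling_log_factorial needs n >= 1")
  n * log(n) - n + 0.5 * log(2 * pi * n) + 1 / (12 * n)
}

# exact ln k! for k = 0..20
.exact_lfact <- cumsum(c(0, log(seq_len(20))))

# ln n! — exact summation for n <= 20, Stirling series above.
log_factorial <- function(n) {
  out <- numeric(length(n))
  small <- n <= 20
  out[small] <- .exact_lfact[n[small] + 1]
  if (any(!small)) out[!small] <- stirling_log_factorial(n[!small])
  out
}

# ln P(X = x) for X ~ Binomial(n, p), via the Stirling path.
binom_log_pmf <- function(x, n, p) {
  if (p <= 0) return(ifelse(x == 0, 0, -Inf))
  if (p >= 1) return(ifelse(x == n, 0, -Inf))
  log_factorial(n) - log_factorial(x) - log_factorial(n - x) +
    x * log(p) + (n - x) * log1p(-p)
}

# One-sided log tail probability. Sums pmf terms outward from `x` in log
# space using the exact multiplicative term ratio, extending the window
# adaptively; when the series is geometric-decaying at the stopping point the
# remainder is closed with the geometric bound term * r / (1 - r).
binom_log_tail <- function(x, n, p, upper) {
  t0 <- binom_log_pmf(x, n, p)
  if (!is.finite(t0)) return(-Inf)
  span <- if (upper) n - x else x
  if (span == 0) return(min(t0, 0))
  sd <- sqrt(max(n * p * (1 - p), 1))
  width <- min(span, max(64L, ceiling(12 * sd)))
  repeat {
    if (upper) {
      xs <- x + seq_len(width) - 1          # x .. x+width-1 are the term indices
      logr <- log(p) - log1p(-p) + log(n - xs) - log(xs + 1)
    } else {
      xs <- x - seq_len(width) + 1
      logr <- log1p(-p) - log(p) + log(xs) - log(n - xs + 1)
    }
    terms <- t0 + c(0, cumsum(logr))
    s <- logspace_sum(terms)
    last <- terms[length(terms)]
    if (width == span) return(min(s, 0))
    if (last < s - 46) {                    # remaining mass is negligible or bounded
      r <- exp(logr[length(logr)])
      if (r < 1) s <- logspace_sum(c(s, last + log(r) - log1p(-r)))
      return(min(s, 0))
    }
    width <- min(span, width * 4L)
  }
}

#' One-sided binomial tail p-value on the log10 scale
#'
#' For each observation, tests the count against Binomial(`n`, `p`) in the
#' direction of its deviation from the mean `n p`: observations at or above
#' the mean are scored with \eqn{P(X \ge x)} (`direction = "over"`), below it
#' with \eqn{P(X \le x)} (`"under"`). Everything is computed in log space
#' (Stirling-series factorials, log-sum-exp accumulation, geometric far-tail
#' bound), so p-values far beyond double-precision underflow remain exact on
#' the log scale. Degenerate `p` of 0 or 1 return the exact answer.
#'
#' @param observed Integer vector of observed counts.
#' @param n Integer vector of trials (recycled).
#' @param p Numeric vector of success probabilities (recycled).
#' @return A tibble with `observed`, `n`, `p`, `expected`, `log10_pvalue`
#'   (\eqn{\le 0}) and `direction` (`"over"`/`"under"`).
#' @export
#' @examples
#' binomial_log10_pvalue(10, 10, 0.5)  # log10 = 10 * log10(0.5)
binomial_log10_pvalue <- function(observed, n, p) {
  len <- max(length(observed), length(n), length(p))
  observed <- rep_len(as.numeric(observed), len)
  n <- rep_len(as.numeric(n), len)
  p <- rep_len(as.numeric(p), len)
  if (any(observed < 0 | observed > n)) abort("observed must lie in [0, n]")
  if (any(p < 0 | p > 1)) abort("p must lie in [0, 1]")
  res <- vapply(seq_len(len), function(i) {
    over <- observed[i] >= n[i] * p[i]
    lp <- binom_log_tail(observed[i], n[i], p[i], upper = over)
    c(lp / log(10), over)
  }, numeric(2))
  tibble(observed = observed, n = n, p = p, expected = n * p,
         log10_pvalue = res[1, ],
         direction = ifelse(res[2, ] == 1, "over", "under"))
}
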