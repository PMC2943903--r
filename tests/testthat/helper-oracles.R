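# Exact one-sided binomial tail on the log10 scale, by brute-force log-space
# summation with exact factorials (cumulative sum of logs). Independent of the
# package's Stirling/geometric-bound production path.
exact_log10_tail <- function(observed, n, p, direction = c("over", "under")) {
  direction <- match.arg(direction)
  lf <- c(0, cumsum(log(seq_len(max(n, 1)))))   # lf[k+1] = log(k!)
  xs <- if (direction == "over") observed:n else 0:observed
  logterms <- lf[n + 1] - lf[xs + 1] - lf[n - xs + 1] +
    xs * log(p) + (n - xs) * log1p(-p)
  m <- max(logterms)
  (m + log(sum(exp(logterms - m)))) / log(10)
}

# Normal-equations OLS oracle: coefficients, R^2 and overall F-test p-value
# computed from first principles.
ols_oracle <- function(x, y, degree) {
  X <- outer(x, 0:degree, `^`)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fitted <- as.vector(X %*% beta)
  ssres <- sum((y - fitted)^2)
  sstot <- sum((y - mean(y))^2)
  r2 <- 1 - ssres / sstot
  df1 <- degree
  df2 <- length(y) - degree - 1
  f <- (sstot - ssres) / df1 / (ssres / df2)
  list(coefficients = as.vector(beta), r2 = r2,
       pvalue = stats::pf(f, df1, df2, lower.tail = FALSE))
}

random_smoothed_distribution <- function(m) {
  p <- stats::rgamma(m, shape = 0.5) + 1e-6
  p / sum(p)
}

write_temp_fastq <- function(reads, gz = FALSE) {
  path <- withr::local_tempfile(fileext = if (gz) ".fastq.gz" else ".fastq",
                                .local_envir = parent.frame())
  write_fastq(reads, path)
  path
}

random_reads <- function(n, len, with_n = FALSE, seed = NULL) {
  withr::with_seed(seed %||% 42L, {
    alpha <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(alpha, len, replace = TRUE), collapse = "")
    }, character(1))
    qc_reads(seqs)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

all_kmers_vec <- function(k) {
  g <- expand.grid(rep(list(c("A", "C", "G", "T")), k),
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  do.call(paste0, rev(g))
}

# Minimal positional_kmers-shaped object with prescribed per-position counts
# for a single k-mer (for exercising the trend fits directly).
fake_positional_kmers <- function(positions, counts, kmer, k) {
  tbl <- tibble::tibble(position = as.integer(positions), kmer = kmer,
                        count = as.integer(counts))
  structure(tbl, k = as.integer(k),
            windows = tibble::tibble(position = as.integer(positions),
                                     n_windows = pmax(as.integer(counts), 1L),
                                     skipped = 0L),
            class = c("positional_kmers", class(tbl)))
}
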