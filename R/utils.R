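#' @importFrom rlang %||% abort warn inform
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

DNA_BASES <- c("A", "C", "G", "T")
BASE_SYMBOLS <- c("A", "C", "G", "T", "N")

# All 4^k k-mers in lexicographic order (A < C < G < T).
all_kmers <- function(k) {
  stopifnot(k >= 1)
  if (k > 12) abort("k > 12 would enumerate more than 16M k-mers")
  g <- expand.grid(rep(list(DNA_BASES), k),
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  do.call(paste0, rev(g))
}

revcomp <- function(x) {
  out <- character(length(x))
  nz <- nchar(x) > 0L
  if (any(nz)) {
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz]))
    )
  }
  out
}

# Uppercase and collapse anything outside {A,C,G,T,N} (IUPAC ambiguity codes,
# stray characters) to N.
sanitize_seq <- function(x) {
  x <- toupper(x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) x[bad] <- gsub("[^ACGTN]", "N", x[bad])
  x
}

# Run code with a temporarily seeded RNG; NULL seed leaves the RNG alone.
with_rng <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

logspace_sum <- function(logx) {
  m <- max(logx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(logx - m)))
}

`%+na%` <- function(a, b) ifelse(is.na(a), b, a)
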