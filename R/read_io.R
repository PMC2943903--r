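#' Construct a read set tibble
#'
#' Builds the tabular read container used throughout the package: one row per
#' read with columns `read_id`, `seq` and `qual` (the raw FASTQ quality
#' string, or `NA` when qualities are unknown). Sequences are uppercased and
#' any character outside `A`, `C`, `G`, `T`, `N` is mapped to `N`, so that `N`
#' can be treated as a fifth base symbol downstream.
#'
#' @param seq Character vector of read sequences.
#' @param read_id Optional character vector of read identifiers; defaults to
#'   `read_1`, `read_2`, ...
#' @param qual Optional character vector of encoded quality strings, same
#'   lengths as `seq`.
#' @param offset Phred encoding offset of `qual` (33 or 64).
#' @return A tibble of class `qc_reads` with attribute `offset`.
#' @export
#' @examples
#' qc_reads(c("ACGT", "GGTA"))
qc_reads <- function(seq, read_id = NULL, qual = NULL, offset = 33L) {
  seq <- as.character(seq)
  n <- length(seq)
  if (n && any(nchar(seq) < 1L)) abort("reads must have length >= 1")
  read_id <- read_id %||% paste0("read_", seq_len(n))
  if (is.null(qual)) {
    qual <- rep(NA_character_, n)
  } else if (!all(is.na(qual)) && any(nchar(qual) != nchar(seq) & !is.na(qual))) {
    bad <- which(nchar(qual) != nchar(seq))[1]
    abort(sprintf("length mismatch between seq and qual at record %d", bad))
  }
  out <- tibble(read_id = as.character(read_id),
                seq = sanitize_seq(seq),
                qual = as.character(qual))
  new_qc_reads(out, offset = as.integer(offset))
}

new_qc_reads <- function(df, offset = 33L) {
  structure(as_tibble(df),
            offset = as.integer(offset),
            class = c("qc_reads", class(as_tibble(df))))
}

#' Detect the Phred quality encoding offset
#'
#' Decides between Phred+33 and Phred+64 from a sample of encoded quality
#' strings. Any ASCII code below 59 forces 33; codes all at or above 64 with
#' at least one above 74 (quality > 41, impossible for old Phred+64 ranges
#' under offset 33 only above 93+33) indicate 64. Samples whose codes all fall
#' in the ambiguous window resolve to 33 with a warning, since modern data is
#' overwhelmingly Phred+33 and a wrongly assumed 64 silently yields negative
#' qualities.
#'
#' @param sample Character vector of quality strings (non-empty).
#' @return Integer 33 or 64, with logical attribute `ambiguous`.
#' @export
#' @examples
#' detect_quality_offset("!!II")
detect_quality_offset <- function(sample) {
  sample <- sample[!is.na(sample) & nchar(sample) > 0L]
  if (!length(sample)) abort("need a non-empty sample of quality strings")
  codes <- utf8ToInt(paste(sample, collapse = ""))
  if (any(codes < 59L)) {
    return(structure(33L, ambiguous = FALSE))
  }
  if (all(codes >= 64L) && any(codes > 74L)) {
    return(structure(64L, ambiguous = FALSE))
  }
  warn("quality offset ambiguous; assuming Phred+33")
  structure(33L, ambiguous = TRUE)
}

#' Read a FASTQ file into a read set
#'
#' Parses 4-line FASTQ records (plain or gzip; `gzfile()` sniffs the magic
#' bytes) into a [qc_reads] tibble. Quality integers are ASCII code minus the
#' offset; `offset = "auto"` detects the encoding from the first records.
#'
#' @param path Path to a FASTQ file (optionally gzip-compressed).
#' @param offset `"auto"`, 33 or 64.
#' @param sample_size Number of records used for auto-detection.
#' @return A `qc_reads` tibble (possibly zero rows) with attribute `offset`.
#' @export
read_fastq <- function(path, offset = c("auto", "33", "64"), sample_size = 10000L) {
  offset <- as.character(offset)
  offset <- match.arg(offset)
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (!length(lines)) {
    return(new_qc_reads(tibble(read_id = character(), seq = character(),
                               qual = character()),
                        offset = if (offset == "auto") 33L else as.integer(offset)))
  }
  if (length(lines) %% 4L != 0L) {
    abort(sprintf("truncated FASTQ: %d lines is not a multiple of 4 (at record %d)",
                  length(lines), length(lines) %/% 4L + 1L))
  }
  idx <- seq(1L, length(lines), by = 4L)
  hdr <- lines[idx]
  seq <- lines[idx + 1L]
  plus <- lines[idx + 2L]
  qual <- lines[idx + 3L]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) abort(sprintf("missing '@' header at record %d", bad[1]))
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) abort(sprintf("missing '+' separator at record %d", bad[1]))
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad)) abort(sprintf("length mismatch at record %d", bad[1]))

  if (offset == "auto") {
    off <- detect_quality_offset(utils::head(qual, sample_size))
    off <- as.integer(off)
  } else {
    off <- as.integer(offset)
  }
  codes_min <- min(utf8ToInt(paste(qual, collapse = "")))
  if (codes_min < off) {
    abort(sprintf("quality character below offset %d (ASCII %d) found", off, codes_min))
  }
  qc_reads(seq, read_id = sub("^@", "", hdr), qual = qual, offset = off)
}

#' Write a read set to FASTQ
#'
#' @param reads A `qc_reads` tibble.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$qual
  if (anyNA(qual)) {
    # reads without qualities get the maximum score so information is not
    # invented downward
    qual[is.na(qual)] <- vapply(nchar(reads$seq[is.na(qual)]),
                                function(n) strrep("~", n), character(1))
  }
  out <- rbind(paste0("@", reads$read_id), reads$seq, "+", qual)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(as.vector(out), con)
  invisible(path)
}

#' Decode Phred quality strings to integer scores
#'
#' @param qual Character vector of encoded quality strings.
#' @param offset Encoding offset (33 or 64).
#' @return A list of integer vectors, one per string.
#' @export
#' @examples
#' phred_decode("IIII")
phred_decode <- function(qual, offset = 33L) {
  lapply(qual, function(q) {
    if (is.na(q)) return(integer())
    utf8ToInt(q) - as.integer(offset)
  })
}

#' Summarise a read set
#'
#' @param reads A `qc_reads` tibble.
#' @return One-row tibble with `n_reads`, `max_length` and a list-column
#'   `length_histogram` (a tibble of `length`, `n`).
#' @export
read_set_summary <- function(reads) {
  lens <- nchar(reads$seq)
  hist <- dplyr::count(tibble(length = lens), .data$length)
  tibble(n_reads = nrow(reads),
         max_length = if (nrow(reads)) max(lens) else 0L,
         length_histogram = list(hist))
}

#' Read a FASTA reference
#'
#' Parses a (multi-record) FASTA file via Biostrings, uppercases sequences and
#' maps any character outside `A`, `C`, `G`, `T`, `N` to `N`.
#'
#' @param path Path to a FASTA file.
#' @return A tibble of class `qc_reference` with columns `seq_id`, `seq`,
#'   `length`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  set <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                  error = function(e) abort(sprintf("not valid FASTA: %s",
                                                    conditionMessage(e))))
  if (!length(set)) abort("empty FASTA file")
  seqs <- sanitize_seq(as.character(set))
  new_qc_reference(tibble(seq_id = names(set) %||% paste0("seq_", seq_along(set)),
                          seq = unname(seqs),
                          length = unname(nchar(seqs))))
}

new_qc_reference <- function(df) {
  structure(as_tibble(df), class = c("qc_reference", class(as_tibble(df))))
}

# Accept a qc_reference tibble (single row), a one-element character vector,
# or a data frame with a seq column; returns the bare sequence string.
ref_sequence <- function(ref) {
  if (is.character(ref) && length(ref) == 1L) return(sanitize_seq(ref))
  if (is.data.frame(ref)) {
    if (!"seq" %in% names(ref)) abort("reference tibble must have a 'seq' column")
    if (nrow(ref) != 1L) {
      abort("supply a single reference sequence (one row); subset or concatenate first")
    }
    return(ref$seq[[1]])
  }
  abort("reference must be a one-row tibble or a single character string")
}
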