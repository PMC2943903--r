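# shared uniform-sampling read sampler: starts uniform over the valid range,
# strand uniform, no errors. Returns sequences plus their provenance.
sample_read_seqs <- function(ref_seq, n, read_length) {
  g <- nchar(ref_seq)
  if (g < read_length) abort("reference shorter than the read length")
  starts <- sample.int(g - read_length + 1L, n, replace = TRUE)
  seqs <- substring(ref_seq, starts, starts + read_length - 1L)
  minus <- stats::runif(n) < 0.5
  seqs[minus] <- revcomp(seqs[minus])
  list(seqs = seqs, starts = starts, strand = ifelse(minus, "-", "+"))
}

# read ids record sampling provenance: <prefix>_<i>:<start>:<strand>
provenance_ids <- function(prefix, sampled) {
  sprintf("%s_%d:%d:%s", prefix, seq_along(sampled$seqs),
          sampled$starts, sampled$strand)
}

# substitution matrix: row = template base, columns = the 3 replacement bases
.subst_other <- rbind(A = c("C", "G", "T"),
                      C = c("A", "G", "T"),
                      G = c("A", "C", "T"),
                      T = c("A", "C", "G"),
                      N = c("A", "C", "G"))

# apply per-position uniform substitution errors in place
apply_substitutions <- function(seqs, error_profile) {
  n <- length(seqs)
  for (j in seq_along(error_profile)) {
    e <- error_profile[j]
    if (e <= 0) next
    hit <- which(stats::runif(n) < e)
    if (!length(hit)) next
    cur <- substr(seqs[hit], j, j)
    repl <- .subst_other[cbind(match(cur, rownames(.subst_other)),
                               sample.int(3L, length(hit), replace = TRUE))]
    substr(seqs[hit], j, j) <- repl
  }
  seqs
}

error_to_phred <- function(e) {
  q <- ifelse(e <= 0, 93, round(-10 * log10(e)))
  as.integer(pmin(pmax(q, 0), 93))
}

#' Simulate reads under the uniform-sampling null with substitution errors
#'
#' Draws `n` read start positions uniformly over the reference, picks a strand
#' uniformly (reverse-complementing on minus), and then applies independent
#' substitution errors: at read position `j` the base is replaced, with
#' probability `error_profile[j]`, by one of the other three bases chosen
#' uniformly. This is exactly the null model against which observed read sets
#' are calibrated — uniform genomic sampling plus context-free random
#' substitution. Emitted qualities are the Phred scores corresponding to the
#' per-position error rates.
#'
#' @param ref Reference: one-row `qc_reference` tibble or character string.
#' @param n Number of reads.
#' @param read_length Read length (all reads identical length).
#' @param error_profile Numeric vector of per-position error probabilities in
#'   `[0, 1]`; a scalar is recycled to `read_length`. Typically
#'   `quality_profile(reads)$mean_error_prob` of the data being calibrated.
#' @param seed Optional integer seed; identical seeds give identical read sets.
#' @return A `qc_reads` tibble; read ids record the sampled start and strand
#'   as `sim_<i>:<start>:<strand>`.
#' @export
simulate_reads <- function(ref, n, read_length, error_profile = 0, seed = NULL) {
  ref_seq <- ref_sequence(ref)
  read_length <- as.integer(read_length)
  if (length(error_profile) == 1L) {
    error_profile <- rep(error_profile, read_length)
  }
  if (length(error_profile) != read_length) {
    abort("error_profile length must equal read_length")
  }
  if (any(error_profile < 0 | error_profile > 1)) {
    abort("error probabilities must lie in [0, 1]")
  }
  with_rng(seed, {
    sampled <- sample_read_seqs(ref_seq, n, read_length)
    seqs <- apply_substitutions(sampled$seqs, error_profile)
    qual <- intToUtf8(error_to_phred(error_profile) + 33L)
    qc_reads(seqs, read_id = provenance_ids("sim", sampled),
             qual = rep(qual, n), offset = 33L)
  })
}

#' Bootstrap calibration of the null KL divergence matrix
#'
#' Simulates `replicates` read sets under the uniform-sampling null with the
#' given error profile, computes the KL matrix of each, and returns the
#' per-cell mean and standard deviation. Observed divergences can then be
#' expressed as effect sizes (standard deviations from the null mean) with
#' [effect_sizes()]. The default of 100 replicates matches standard practice
#' for this calibration; replicate `r` is seeded with `seed + r` so runs are
#' reproducible cell for cell.
#'
#' @inheritParams simulate_reads
#' @param replicates Number of simulated read sets (`>= 2`; default 100).
#' @param k K-mer length for the divergence analysis (default 6).
#' @param alpha Smoothing pseudocount passed to [kl_matrix()].
#' @param min_coverage Coverage floor passed to [kl_matrix()].
#' @param seed Master seed; replicate `r` uses `seed + r`.
#' @return Object of class `null_calibration`: `mean` and `sd` matrices,
#'   `avg_sd` (mean off-diagonal sd), `avg_sd_ci95` (normal-approximation 95%
#'   interval across cells), `positions`, `replicates`, `k`, `alpha`.
#' @export
calibrate_null <- function(ref, n, read_length, error_profile = 0,
                           replicates = 100L, k = 6L, alpha = 0.5,
                           min_coverage = 1, seed = NULL) {
  replicates <- as.integer(replicates)
  k <- as.integer(k)
  if (replicates < 2L) abort("need at least 2 replicates for a standard deviation")
  seed <- seed %||% sample.int(.Machine$integer.max - replicates, 1L)
  acc <- NULL; acc2 <- NULL; positions <- NULL
  for (r in seq_len(replicates)) {
    reads <- simulate_reads(ref, n, read_length, error_profile, seed = seed + r)
    km <- kl_matrix(count_kmers_by_position(reads, k), alpha = alpha,
                    min_coverage = min_coverage)
    if (is.null(acc)) {
      positions <- km$positions
      acc <- km$values; acc2 <- km$values^2
    } else {
      if (!identical(km$positions, positions)) {
        abort("replicates produced differing position sets")
      }
      acc <- acc + km$values; acc2 <- acc2 + km$values^2
    }
  }
  mean_m <- acc / replicates
  var_m <- pmax(acc2 / replicates - mean_m^2, 0) * replicates / (replicates - 1)
  sd_m <- sqrt(var_m)
  off <- row(sd_m) != col(sd_m)
  avg_sd <- mean(sd_m[off])
  se <- stats::sd(sd_m[off]) / sqrt(sum(off))
  structure(list(mean = mean_m, sd = sd_m, positions = positions,
                 replicates = replicates, k = k, alpha = alpha,
                 avg_sd = avg_sd,
                 avg_sd_ci95 = c(lower = avg_sd - 1.96 * se,
                                 upper = avg_sd + 1.96 * se)),
            class = "null_calibration")
}

#' @export
print.null_calibration <- function(x, ...) {
  cat(sprintf(paste0("Null KL calibration: %d replicates, k = %d, %d positions\n",
                     "mean off-diagonal KL %.4g bits; avg sd %.4g ",
                     "(95%% CI %.4g-%.4g)\n"),
              x$replicates, x$k, length(x$positions),
              offdiag_mean(x$mean), x$avg_sd,
              x$avg_sd_ci95[1], x$avg_sd_ci95[2]))
  invisible(x)
}

#' @rdname calibrate_null
#' @param x A `null_calibration` object.
#' @param ... Unused.
#' @method glance null_calibration
#' @export
glance.null_calibration <- function(x, ...) {
  tibble(replicates = x$replicates, k = x$k, n_positions = length(x$positions),
         mean_offdiag_kl = offdiag_mean(x$mean), avg_sd = x$avg_sd,
         avg_sd_ci95_lower = unname(x$avg_sd_ci95[1]),
         avg_sd_ci95_upper = unname(x$avg_sd_ci95[2]))
}

#' Effect sizes of observed KL divergences against a null calibration
#'
#' `z[i, j] = (observed[i, j] - mean[i, j]) / sd[i, j]`: how many null
#' standard deviations each observed divergence sits from its simulated
#' expectation. Cells with zero null sd (the diagonal, or degenerate cells)
#' are listed rather than given a fabricated number.
#'
#' @param observed A `kl_matrix`.
#' @param calibration A `null_calibration` over the same positions and `k`.
#' @return Object of class `effect_size_matrix`: `z` matrix (NA in degenerate
#'   cells) and `degenerate` tibble of (from, to) cells with zero sd.
#' @export
effect_sizes <- function(observed, calibration) {
  if (!identical(observed$positions, calibration$positions) ||
      !identical(dim(observed$values), dim(calibration$mean))) {
    abort("observed matrix and calibration have mismatched shapes")
  }
  if (!identical(observed$k, calibration$k)) abort("k mismatch")
  zero_sd <- calibration$sd == 0
  z <- (observed$values - calibration$mean) / calibration$sd
  z[zero_sd] <- NA_real_
  deg <- which(zero_sd, arr.ind = TRUE)
  structure(list(z = z, positions = observed$positions,
                 degenerate = tibble(from = observed$positions[deg[, 1]],
                                     to = observed$positions[deg[, 2]])),
            class = "effect_size_matrix")
}

#' @export
print.effect_size_matrix <- function(x, ...) {
  zz <- abs(x$z)
  i <- which(zz == max(zz, na.rm = TRUE), arr.ind = TRUE)[1, ]
  cat(sprintf("Effect sizes: max |z| = %.2f at (%d, %d); %d degenerate cells\n",
              max(zz, na.rm = TRUE), x$positions[i[1]], x$positions[i[2]],
              nrow(x$degenerate)))
  invisible(x)
}

#' @rdname effect_sizes
#' @param x An `effect_size_matrix` object.
#' @param ... Unused.
#' @method tidy effect_size_matrix
#' @export
tidy.effect_size_matrix <- function(x, ...) {
  long <- as_tibble(as.data.frame.table(x$z, stringsAsFactors = FALSE))
  names(long) <- c("from", "to", "z")
  long <- dplyr::mutate(long, from = as.integer(.data$from),
                        to = as.integer(.data$to))
  # dimnames may be absent when the calibration matrices carried none
  if (all(is.na(long$from))) {
    grid <- expand.grid(from = x$positions, to = x$positions)
    long$from <- grid$from; long$to <- grid$to
  }
  long
}

#' @rdname effect_sizes
#' @method glance effect_size_matrix
#' @export
glance.effect_size_matrix <- function(x, ...) {
  zz <- abs(x$z)
  i <- which(zz == max(zz, na.rm = TRUE), arr.ind = TRUE)[1, ]
  tibble(max_abs_z = max(zz, na.rm = TRUE),
         argmax_from = x$positions[i[1]], argmax_to = x$positions[i[2]],
         prop_abs_z_lt_4 = mean(zz < 4, na.rm = TRUE),
         n_degenerate = nrow(x$degenerate))
}
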