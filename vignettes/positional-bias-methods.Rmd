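---
title: "Detecting positional bias in short reads: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting positional bias in short reads: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readbias)
```

## The null model

Three idealising assumptions are commonly made about whole-genome shotgun
read sets, and `readbias` is built to test each of them.

**Uniform sampling.** Every genome position is equally likely to start a
read, on either strand. If a k-mer `w` occurs `m_w` times among the `n_sites`
windows of the genome (both strands), a read carries `w` at any given offset
with probability `p_w = m_w / n_sites`, and the count of `w` at a fixed read
position across `N` reads is Binomial(`N`, `p_w`).

**Position independence.** A consequence of uniform sampling: a k-mer's
frequency should not depend on *where* in the read it is measured. Edge
effects at the ends of the genome are of order read-length / genome-length
and are neglected.

**Context-free substitution errors.** Errors replace a base with one of the
other three uniformly, independent of sequence context; error *rates* may
vary along the read (they typically rise toward the end), but the
substitution itself is unstructured.

Violations surface in three complementary statistics: per-position base-call
profiles, binomial tail tests of positional k-mer counts, and the pairwise
Kullback-Leibler (KL) divergence of per-position k-mer distributions,
calibrated by simulation under the null.

## Parameters that matter

| parameter | default | where | meaning |
|---|---|---|---|
| `k` | 6 | k-mer tests, KL | window length; 6 balances specificity against sampling depth — 4^k cells must be populated by the available windows, so large `k` dilutes counts and weakens significance, while small `k` loses sequence specificity. The base-call profile is the `k = 1` special case. |
| `alpha` | 0.5 | `position_distribution`, `kl_matrix` | additive pseudocount per k-mer. KL is undefined when the encoding distribution has a zero where the true one does not; smoothing both distributions guarantees shared support. `alpha = 0` is available when raw empirical distributions are wanted. |
| `min_coverage` | 1000 | `kl_matrix` | positions with fewer valid windows are dropped, so noise-dominated final cycles (or rare long reads in variable-length sets) do not contaminate the matrix. |
| `replicates` | 100 | `calibrate_null` | bootstrap read sets; the per-cell sd has ~`replicates − 1` degrees of freedom, so effect sizes from small calibrations (10–20 replicates) carry visibly heavier tails. |
| `max_non_a` | 5% of read length | `filter_polya` | a read is a poly-A artefact when at most this many bases are non-A. No canonical cut-off exists; 5% removes flow-cell reflection artefacts without touching genuinely A-rich genomic reads. |
| `max_mismatch` | 1 | `filter_primer_prefix` | primer-prefix mismatch budget over the full primer length, scaled proportionally for reads shorter than the primer. `N` counts as a mismatch. |

Positions are 1-based everywhere a user sees them.

## Numerical choices

**Log-space binomial tails.** Significant positional biases produce p-values
far below double-precision underflow (the worked example in the README
reaches 10^-4408), so nothing is ever exponentiated. The tail is summed
outward from the observation using the exact term ratio
`r_x = p (n − x) / ((x + 1)(1 − p))`, accumulated by log-sum-exp over an
adaptively grown window; when the series is decaying at the stopping point
the remainder is closed with the geometric bound `term · r / (1 − r)`.

**Stirling series with the 1/(12n) term.** Factorials anchor each tail at a
single log-pmf evaluation, so that anchor's accuracy bounds the whole
p-value. `log n!` is summed exactly for `n ≤ 20` and approximated by
`n ln n − n + ½ ln(2πn) + 1/(12n)` above. Including the `1/(12n)` term drops
the residual from ~`1/(12n)` to ~`1/(360 n³)`: at `n = 100` that is the
difference between ~0.002 and ~10^-7 on the log10 scale, and only the latter
holds the production path inside its 10^-3 relative-accuracy contract
against exact summation for central observations.

**Zero-probability background k-mers.** A k-mer observed in reads but absent
from the reference background would need `log 0`. Its probability is floored
at `1 / (2 n_sites)` — half a count — which stays conservative while still
reporting the observation as the extreme event it is.

**One-sided, direction-labelled tests.** Over- and under-representation are
reported separately (no doubling); Bonferroni correction runs over all
(k-mer × position) tests actually performed, and both raw and corrected
log10 values are emitted.

**Trend fits on raw counts.** Positional trends of single k-mers are
ordinary least squares of raw counts on position at degree 1 or 3 (`"auto"`
keeps the better adjusted R²). Constant counts are flagged degenerate with
`r² = 0`, p-value 1, rather than producing a 0/0. Fitting raw counts rather
than log counts keeps zero counts representable and the residual structure
interpretable against the binomial sampling noise.

**Diagonal and negative dust.** The KL matrix diagonal is exactly zero by
construction; off-diagonal entries below zero by less than 10^-9
(floating-point dust on near-identical distributions) are clamped to zero,
since Gibbs' inequality guarantees non-negativity on shared support.

**Quality offsets.** Any ASCII code below 59 forces Phred+33; codes all at
or above 64 with at least one above 74 indicate Phred+64; fully ambiguous
samples resolve to 33 with a warning, because modern data is overwhelmingly
Phred+33 and a wrong 64 silently yields negative qualities. Characters
outside `{A,C,G,T,N}` (lowercase, IUPAC ambiguity codes) are mapped to `N`,
which is counted as a first-class fifth symbol in base-call profiles and
excluded (but tallied) from k-mer windows.

## The simulator and what the bootstrap calibrates

`simulate_reads()` implements the null directly: uniform starts, uniform
strand, per-position substitution rates taken from the data's own mean error
probabilities (`quality_profile()$mean_error_prob`, which averages
`10^(-Q/10)` per base rather than converting the mean quality — the former
is the unbiased error rate). Each calibration replicate uses seed
`master + r`, so runs are reproducible cell for cell. Matching `n` to the
observed read count preserves the coverage ratio, and using a reference for
the bootstrap preserves genome complexity.

The error profile is a deliberate simplification: per-position *mean* error
probabilities rather than resampled per-read quality strings, and no
quality-dependent miscall structure (e.g. the G-to-T confusion reported for
some base callers) or indels. The calibration therefore answers "what would
uniform sampling plus unstructured substitution produce?", which is exactly
the null being tested — not "what does this instrument's error process look
like?".

A rising error profile produces a characteristic null surface: divergence
between early and late positions grows with the error-rate gap because
substitutions blur a non-uniform genomic k-mer distribution toward
uniformity. Note this requires compositional skew to exist at all — on a
50% GC i.i.d. genome the k-mer distribution is already uniform and
substitution errors move nothing. The package's own shape check therefore
runs on a 30% GC genome, where the effect is unambiguous at desk scale.

## What the synthetic fixtures emulate — and what they do not

`generate_genome()` draws i.i.d. bases at a chosen GC content;
`generate_reads()` samples under the null and then injects biases by
overwriting bases post-sampling, which keeps the genome composition clean
and makes every injected effect exactly computable:

* `start_motif` — a fraction of reads begin with a fixed motif (adapter or
  site-selection bias at the read start);
* `position_enrichment` — a k-mer's frequency at one position is raised to a
  target fold of its empirical level;
* `polyrun_error` — windows one substitution away from a pure run are
  converted to the run with a given probability in the tail windows,
  emulating the systematic near-run-to-run error conversion that inflates
  poly-base counts at read ends;
* `error_gradient` — linearly interpolated per-position substitution rates.

Real data differs in ways these fixtures deliberately omit: genomic repeat
structure and long-range composition, PCR amplification bias, platform
homopolymer indels, correlated errors within a cycle, and per-read quality
variation. Passing the suite therefore demonstrates that each detector
recovers the effect it targets at realistic sizes and that false-positive
rates are controlled under the stated null — not that the null describes any
particular instrument.

## Problem sizes used in the checks

The package's statistical checks run on 100 kb genomes with 50k–100k reads
of length 51 (matching a typical early-platform read length), k = 3 for
dense-coverage calibration checks and k = 6 for motif recovery, with 10–20
bootstrap replicates. These sizes give every test comfortable statistical
margins — e.g. an injected 5% start motif sits thousands of log10 units
beyond its threshold — while keeping a full run in the low minutes on one
CPU. The calibration default of 100 replicates is recommended for real
analyses.

## Design decisions on genuinely open points

* **Whole-read primer removal.** Reads matching the primer prefix are
  removed entirely rather than trimmed. Trimming would leave variable-length
  3' fragments whose windows re-enter the positional statistics at shifted
  offsets; removal keeps the accounting exact. Trimming remains a reasonable
  alternative when yield matters more than positional purity.
* **Background denominator.** Reference backgrounds define
  `p_w = m_w / n_sites` over all valid windows counted (both strands doubles
  both numerator and denominator). The read-pool background pools windows
  over all positions.
* **Internal simulator.** The bootstrap uses the package's own sampler
  rather than an external read-simulation tool, so the simulated process is
  exactly the null stated above, with no hidden platform model.
* **N handling in quality statistics.** N bases keep their quality values in
  the profile; they are excluded from k-mer windows but counted in the
  per-position `skipped` tally, so window accounting always balances.

## Known limitations

* KL estimates carry a positive sampling-plus-smoothing floor of roughly
  `4^k / (2 N ln 2)` bits per pair; comparisons should always be made
  against the bootstrap calibration, never against zero. The effect-size
  machinery does this automatically.
* The binomial tests assume reads are independent draws; heavy PCR
  duplication violates this and inflates significance.
* Variable-length read sets are supported throughout (per-position
  denominators use covering reads only), but positions below the coverage
  floor silently leave the KL matrix — check `kl_matrix()$dropped`.
* The CLI's `report` exit status reflects execution success only; the QC
  verdict lives in `summary.json` (`flags`, `bias_detected`). The headline
  flags use fixed thresholds (Bonferroni 0.01; base-call couple difference
  0.03; first-row KL ratio 2) chosen for clear separation on fixtures of
  ~20k reads and above; they are configuration parameters, not laws.
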