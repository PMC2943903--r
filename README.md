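# readbias

Reference-free statistical quality control for short-read sequencing data.

Short reads are routinely assumed to start uniformly across the sequenced
genome and to carry only context-free substitution errors. Real data from
high-throughput platforms violates both assumptions: some k-mers are
dramatically over- or under-represented at particular read positions,
poly-base runs accumulate toward read ends through systematic error
conversion, and the k-mer distribution at the first read positions can differ
sharply from everywhere else. `readbias` quantifies these biases from the
reads alone — no reference is required, though one sharpens the background
model — so that problems can be found *before* assembly, resequencing or
coverage-sensitive analyses. It is aimed at anyone triaging FASTQ data:
sequencing cores, assembly pipelines, methods developers.

## The statistics

Three progressively deeper views of a read set, plus a calibration layer:

1. **Base-call profiles.** Counts of each base symbol (A, C, G, T, N) at every
   read position, with the complementary-couple differences A−T and C−G as
   strand-symmetry diagnostics. Unbiased whole-genome data should be flat in
   position and symmetric in each couple.

2. **Positional k-mer tests.** Let `p_w` be the probability of k-mer `w`
   under a background model (reference windows or the pooled read windows)
   and `n` the number of valid windows at a read position. Under uniform
   sampling the count `X_w` is Binomial(`n`, `p_w`); each observation is
   scored with a one-sided tail probability in its deviation direction,

       P(X >= x)  or  P(X <= x),   X ~ Bin(n, p_w),

   computed entirely in log space with Stirling-series factorials, so
   p-values like 10^-4000 are exact on the log10 scale. Bonferroni-corrected
   values are reported alongside the raw ones. Positional trends of single
   k-mers (e.g. poly-G) are summarised by linear/cubic least-squares fits.

3. **KL divergence of positional spectra.** With `P_i` the (smoothed)
   distribution of all 4^k k-mers at position `i`,

       KL(P_i || P_j) = sum_w P_i(w) log2( P_i(w) / P_j(w) )   [bits]

   is computed for every ordered position pair. Biased positions stand out as
   bright rows/columns of the matrix.

4. **Bootstrap calibration.** A built-in simulator draws read sets under the
   null (uniform starts, uniform strand, per-position substitution errors
   from the data's own quality profile), the KL matrix is recomputed per
   replicate, and observed divergences are reported as effect sizes
   `z = (observed − null mean) / null sd` rather than p-values.

Artefact filters (poly-A fragments, primer prefixes) and synthetic
genome/read generators with parameterised injected biases (start motifs,
positional enrichment, poly-run error conversion, error gradients) complete
the toolkit; the generators make every detector testable end to end.

## Worked example

Inject a start-site bias into synthetic reads — 5% of reads forced to begin
with `ACGTAC` — and recover it:

```r
library(readbias)

genome <- generate_genome(100000, gc = 0.5, seed = 101)
reads  <- generate_reads(genome, 50000, 51,
                         bias = bias_spec(start_motif = list(motif = "ACGTAC",
                                                             fraction = 0.05)),
                         seed = 102)

pk <- count_kmers_by_position(reads, k = 6)
bg <- background_from_reference(genome, k = 6, both_strands = TRUE)
head(test_positional_kmers(pk, bg, positions = "start"), 3)
#> # A tibble: 3 × 9
#>   kmer   position observed     n        p expected log10_pvalue direction bonferroni_log10
#>   <chr>     <int>    <int> <int>    <dbl>    <dbl>        <dbl> <chr>                <dbl>
#> 1 ACGTAC        1     2488 50000 0.000320     16.0     -4408.   over             -4405.
#> 2 ATGTCT        1        1 50000 0.000235     11.8        -4.00 under               -0.386
#> 3 ACACGC        1       23 50000 0.000205     10.3        -3.38 over                 0
```

The injected motif is observed 2488 times at position 1 against an expected
16 — a log10 p-value of −4408, thousands of orders of magnitude beyond any
threshold — while the runner-up k-mers sit at ordinary chance levels after
Bonferroni correction. The divergence analysis sees the same structure
without any background model:

```r
km <- kl_matrix(pk, alpha = 0.5, min_coverage = 1000)
km
#> KL divergence matrix: k = 6, 46 positions, alpha = 0.5
#> off-diagonal mean 0.1341 bits, max 0.4974 bits

cal <- calibrate_null(genome, n = 50000, read_length = 51, error_profile = 0,
                      replicates = 10, k = 6, seed = 103)
glance(effect_sizes(km, cal))
#> # A tibble: 1 × 5
#>   max_abs_z argmax_from argmax_to prop_abs_z_lt_4 n_degenerate
#>       <dbl>       <int>     <int>           <dbl>        <int>
#> 1      231.           1        29           0.786           46
```

The largest effect size (231 null standard deviations) involves position 1,
and the cells exceeding |z| = 4 are exactly those whose windows overlap the
six overwritten bases — on unbiased fixtures ≥ 99% of cells stay inside
|z| < 4. `autoplot(km)` renders the matrix as a heat map;
`run_full_report(qc_config(...))` chains filtering, profiling, testing and
divergence analysis into TSV tables plus a JSON summary with headline flags,
and the `exec/readbias` script exposes every stage as a shell subcommand
(`basecalls`, `kmers`, `kldiv`, `bootstrap`, `filter`, `simulate`, `synth`,
`report`).

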