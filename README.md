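# antisenser

Characterisation of antisense transcription from stranded genome
annotations. The package is written for transcriptomics researchers who
have assembled stranded transcript models (e.g. from a directional RNA-seq
library) and want to ask, without any external databases, four questions
about the transcripts that overlap protein-coding genes on the opposite
strand:

1. **What kinds of antisense configurations are present?** Every pair of
   opposite-strand overlapping transcripts is assigned to one of five
   classes: *intronic* (the antisense transcript, AST, is fully embedded in
   a single intron of its host gene), *nested* (at least one AST exon in a
   host intron, without full embedding), *exonic* (coding parts overlap),
   and *3'-UTR* / *5'-UTR* overlap (tail-to-tail / head-to-head overlap
   without shared coding parts).
2. **Do ASTs encode proteins?** The number of ASTs with orientation-correct
   homology hits (e.g. BLASTX against a proteome, reverse-frame hits
   removed) is compared with a null built by resampling length-matched
   transcript sets: AST lengths are cut into 20 quantile bins (5 % of ASTs
   each) and each of 1000 resamples draws a bin-size-matched sample from
   all transcripts in the bin's length range. The empirical p-value is
   `(1 + #{null ≥ observed}) / (reps + 1)`.
3. **Are host and AST expression coupled?** Spearman's ρ across expression
   samples is computed per antisense gene pair and the distribution is
   compared to randomly drawn gene pairs (two-sample Kolmogorov–Smirnov
   statistic plus quantile table).
4. **Is the antisense arrangement conserved in other genomes?** A pair is
   called conserved in a target genome when the leftmost-to-rightmost span
   of the host gene's homology hits (per contig and strand, e-value
   < 0.001) contains at least one AST hit on the opposite strand.

A Wilcoxon rank-sum module compares largest-intron-per-gene distributions
(host vs non-host genes) and antisense pair spans vs conserved synteny
block sizes, and a conserved non-coding element (CNE) screen extracts
non-coding, non-repetitive regions ≥ 100 bp by mask complementation and
counts cross-genome BLASTN matches.

Because all of this is usually run on data that takes days to produce, the
package ships a synthetic-data generator that plants every configuration
with known ground truth (annotation geometry, copula-controlled expression
correlation, length-dependent evidence probabilities, a planted
conservation matrix), so the entire pipeline is testable end to end in
seconds.

## Worked example

```r
library(antisenser)

cfg <- simulation_config(seed = 11)       # 200 background genes,
                                          # planted 20/10/8/6/4 classes
dir <- tempfile(); out <- tempfile()
simulate_bundle(cfg, dir)                 # GFF3 + expression + hit tables
report <- run_antisense_pipeline(dir, out, seed = 5)

report$classify[c("n_intronic", "n_nested", "n_exonic", "n_utr3", "n_utr5")]
#> $n_intronic
#> [1] 20
#> $n_nested
#> [1] 10
#> $n_exonic
#> [1] 8
#> $n_utr3
#> [1] 6
#> $n_utr5
#> [1] 4

report$enrich[c("observed", "null_mean", "p_high")]
#> $observed
#> [1] 4
#> $null_mean
#> [1] 4.65
#> $p_high
#> [1] 0.7722278

unlist(report$introns[c("p", "host_median", "nonhost_median")])
#>              p    host_median nonhost_median
#>   1.450581e-13   2.585000e+03   3.180000e+02
```

The classifier recovers exactly the planted class counts. The enrichment
p-value is non-significant because the default generator plants no
evidence enrichment (ratio 1): ASTs carry protein hits at the same
length-conditional rate as everything else. The intron comparison shows
the planted effect — host genes draw their introns from a long-tailed
model, and their median largest intron (~2.6 kb) dwarfs the background
(~0.3 kb), with a vanishing one-sided rank-sum p.

Individual steps are ordinary data-frame functions and compose with the
pipe: `read_annotation()` |> `classify_antisense()` |>
`summarize_antisense()`; fitted results have `tidy()`, `glance()` and
`autoplot()` methods.

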