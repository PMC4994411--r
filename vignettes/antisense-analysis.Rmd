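---
title: "Classifying and testing antisense transcription with antisenser"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying and testing antisense transcription with antisenser}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antisenser)
library(dplyr)
```

## The problem

Directional RNA-seq routinely reveals transcripts on the strand opposite a
protein-coding gene. Whether such antisense transcripts (ASTs) are
regulatory non-coding RNAs or simply protein-coding genes that happen to
sit inside another gene's intron cannot be decided from the overlap alone:
it takes (i) a careful geometric classification of the overlap, (ii) a
length-controlled test for protein-coding evidence, (iii) a comparison of
host/AST expression coupling against random gene pairs, and (iv) a
cross-genome test of whether the arrangement is conserved. `antisenser`
implements these four analyses over plain tabular inputs (GFF3/GTF
annotations, BLAST-style tabular hits, gene-by-sample expression TSVs,
BED masks), plus the rank-based comparisons that link them (host genes
vs background genes by largest intron; antisense pair spans vs conserved
synteny block sizes).

All genomic intervals are held 0-based half-open internally; file I/O
converts to and from the 1-based closed convention of GFF/GTF and the
printed coordinates of BLAST tabular output (a subject hit with
`sstart > send` marks a minus-strand subject; a negative query frame marks
a reverse-orientation query).

## The overlap taxonomy

For each unordered pair of same-contig, opposite-strand transcripts whose
spans share at least 1 bp, classification walks a precedence ladder.
Both orderings are tried for the asymmetric classes:

* **intronic** — the candidate AST's genomic span lies entirely within a
  single intron of the host. This is the antisense gene pair proper; the
  host intron index and length are recorded.
* **nested** — at least one AST exon lies entirely within a host intron,
  but the AST as a whole does not.

If neither ordering fires, the symmetric classes are evaluated once:

* **exonic** — the coding parts overlap (CDS when both transcripts carry
  one, exons otherwise), or the overlap matches no terminal pattern.
* **utr3** — exon overlap confined to the 3'-terminal exons of both
  transcripts, coding parts disjoint, convergent (tail-to-tail) geometry.
* **utr5** — the same with 5'-terminal exons and divergent (head-to-head)
  geometry.

Design choices worth stating explicitly, since assembler output often
lacks CDS annotation:

* The 3'-terminal exon is defined by transcription direction — last exon
  in genome order on `+`, first on `-`.
* Without CDS on both sides, UTR classes are assigned purely by
  terminal-exon geometry; a single-exon/single-exon overlap is resolved by
  whether the pair converges (utr3), diverges (utr5), or one span contains
  the other (exonic).
* Precedence intronic > nested > exonic/UTR, because nesting explicitly
  excludes full embedding and the UTR classes explicitly exclude shared
  coding parts.
* Two transcripts can each be nested in the other (interleaved exons);
  both records are emitted. Mutual *intronic* assignment is geometrically
  impossible and treated as an internal error.
* Classification is per transcript pair; deduplication to unique AST
  transcripts, unique host genes and unique (host gene, AST gene) pairs
  happens only in `summarize_antisense()`, matching the three levels at
  which embedded antisense transcription is usually reported.

A note on symmetries: translation of all coordinates and
reverse-complementation of the contig (reflect coordinates *and* swap
strands) leave all labels unchanged. Swapping strands alone turns a
convergent pair into a divergent one, so it maps utr3 and utr5 onto each
other while fixing the other classes — the property suite asserts exactly
this, and the classifier is additionally checked base-by-base against a
brute-force oracle on hundreds of random annotations.

## Protein evidence by length-matched resampling

Longer transcripts are more likely to have a homology hit, so a raw
comparison of hit rates between ASTs and other transcripts is confounded
by length. The test therefore:

1. keeps only orientation-correct hits (`query_frame > 0`) at
   `evalue <= 0.001` (configurable) and flags each transcript with at
   least one such hit;
2. cuts AST spliced lengths into `n_bins = 20` quantile bins (5 % of ASTs
   each, order-statistic edges; tied lengths merge bins; the outer edges
   are the AST length extremes, so transcripts outside the AST length
   range are never sampled);
3. draws, per resample and per bin, a bin-size-matched sample **without
   replacement** from all transcripts in the bin's length range — ASTs
   included — and records the flagged count; resamples (default
   `reps = 1000`) are independent;
4. reports both one-sided empirical p-values with the add-one estimator
   `(1 + #{null ≥ obs}) / (reps + 1)`, which cannot return zero.

The statistic is "transcripts with at least one qualifying hit", not the
summed hit count, because one transcript can produce many redundant HSPs.

## Expression coupling

Spearman's ρ (midrank ties) per antisense gene pair across samples
(≥ 3 required; constant rows yield an undefined correlation and are
dropped with a count). The null is built from uniformly drawn distinct
gene pairs, excluding the antisense pairs themselves. Because the original
comparison of these distributions is visual, the package quantifies it
with a two-sample Kolmogorov–Smirnov statistic plus a 5/25/50/75/95 %
quantile table — reported as a surrogate, not as a calibrated hypothesis
test of "no regulation".

## Conservation by span containment

For each target genome, and per (contig, strand): the span from the
leftmost to the rightmost passing host hit (`evalue < 0.001`, strict, as
is conventional for such screens). A pair is conserved if at least one
passing AST hit lies entirely inside such a span on the opposite strand.
The existential reading (one witness hit suffices) is deliberate:
alignment fragmentation splits real homologies into several partial hits,
so requiring all AST hits inside the span would punish good assemblies.
Cells without host hits are reported `conserved = FALSE` with
`host_detected = FALSE` so host loss can be told apart from loss of the
antisense arrangement; cells with *missing tables* are `NA`, not `FALSE`.

## Rank-sum comparisons

`rank_sum_test()` reports the Mann–Whitney U with midrank ties. For
`n1 + n2 <= 16` without ties the p-value is exact; beyond that the normal
approximation with tie-corrected variance and continuity correction is
used (the sample sizes these comparisons meet in practice are far beyond
the exact range; the exact branch exists for verifiability, and the suite
checks it against full enumeration of arrangements). Genes whose
transcripts are all single-exon are excluded from largest-intron
comparisons by default — a zero-length "largest intron" is not a length.

## What the generator emulates — and what it does not

`simulation_config()` fixes the study conditions: 200 background genes
plus planted counts (intronic 20, nested 10, exonic 8, utr3 6, utr5 4) —
a scale at which every property is testable in seconds while preserving
the dominance of the intronic class seen in real stranded transcriptomes;
50 expression samples (a typical developmental profile panel); a
20-genome conservation screen; `reps = 1000`, 20 length bins, e-value
0.001, 100 bp minimum CNE length as the analysis defaults.

* **Annotation geometry.** Exon and intron lengths are log-normal (heavy
  right tail, as in real annotations). Intronic host genes draw introns
  from a longer-tailed model (defaults put ~5 % of host largest introns
  above 5 kb), and the designated intron is resampled until the planted
  AST fits with margin — infeasible configurations error before emission.
  Planted units are placed with intergenic gaps so no unplanted
  opposite-strand overlap can arise; the classifier therefore must recover
  the planted counts exactly.
* **Expression.** Planted pairs are drawn from a Gaussian copula with
  parameter `r = 2 sin(pi * rho_s / 6)`, which targets the population
  Spearman correlation exactly; marginals are log-normal. The default
  target is ρ = 0, the uncorrelated regime reported for real host/AST
  pairs.
* **Protein evidence.** Hit probability is logistic in log length (base
  rate 0.3 at the midpoint) times an enrichment ratio for ASTs (default 1,
  i.e. the calibration null). Reverse-frame decoy rows exercise the
  orientation filter.
* **Conservation.** Conserved cells get host hits spanning a region plus
  a single opposite-strand witness inside it; non-conserved cells get one
  of three recorded failure modes (no AST hit, hit outside the span, hit
  on the same strand). Witness hits are dropped with probability
  `hit_dropout`; host hits are never dropped, so recall on conserved
  cells is exactly `1 - hit_dropout` — the quantity the recall checks
  measure.

What passing tests on this generator do **not** show: robustness to
mis-assembled transcript models, soft intron boundaries, overlapping gene
dense regions beyond the planted geometries, non-monotone
length–evidence relationships, or paralogy-confounded homology hits. The
generator produces clean truth; real data will be noisier in ways the
synthetic conditions deliberately do not model.

## Numerical and degenerate-input conventions

* Half-open intervals make abutting features non-overlapping; minimum
  overlap is 1 bp, with no expression floor at classification time.
* Corrupt transcripts with overlapping exons are repaired by merging,
  with a warning; unstranded transcripts are rejected with a warning
  (every analysis here is strand-aware).
* Empty inputs flow through: an empty annotation file is an empty set, an
  empty hit table gives zero spans and an all-false/absent matrix.
* All stochastic stages take explicit integer seeds; the pipeline derives
  per-stage sub-seeds by hashing the master seed with the stage name, so
  adding a stage never changes another stage's draws, and reports carry
  no timestamps — a rerun is byte-identical.

## Worked end-to-end run

```{r pipeline, eval = FALSE}
cfg <- simulation_config(seed = 11)
bundle <- tempfile(); out <- tempfile()
simulate_bundle(cfg, bundle)
report <- run_antisense_pipeline(bundle, out, seed = 5)
str(report$classify)
```

The problem sizes used throughout the test suite — 500 random annotations
for the classifier oracle, 400 simulated datasets for resampling
calibration, 2000 simulations for rank-sum null uniformity, 1000 random
hit tables for the conservation oracle — were chosen so each property is
estimated with useful precision while the whole suite stays quick to run.

## Known limitations

* The classifier trusts exon models; it does not attempt to repair or
  re-assemble transcripts, and UTR classes for CDS-less models are a
  geometric convention, not a biochemical call.
* The KS comparison of correlation distributions is descriptive; its p
  assumes independent draws, which multiple pairs sharing a host gene
  violate mildly.
* The conservation call is presence/absence per genome; it does not
  score partial conservation or attempt orthology confirmation.
* Synteny block coordinates and orthology assignments are consumed as
  inputs; computing them is out of scope.
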