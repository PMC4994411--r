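# Rank-based comparisons: host vs non-host largest introns, antisense
# pair spans vs conserved synteny block sizes.

#' Largest intron per gene
#'
#' For every gene, the maximum intron length over all its transcripts'
#' introns (0 for genes whose transcripts are all single-exon). Intron-less
#' genes are excluded from host/non-host comparisons by default because a
#' zero-length "largest intron" is not a length.
#'
#' @param a An [annotation_set()].
#' @param host_genes Optional character vector of host gene ids (e.g. the
#'   `host_gene` column of the intronic records of [classify_antisense()]);
#'   sets the `is_host` flag.
#' @return Tibble `gene_id`, `is_host`, `largest_intron`.
#' @export
largest_intron_per_gene <- function(a, host_genes = character()) {
  intr <- derive_introns(a) %>%
    left_join(select(a$transcripts, "transcript_id", "gene_id"),
              by = "transcript_id") %>%
    group_by(.data$gene_id) %>%
    summarise(largest_intron = max(.data$length), .groups = "drop")
  a$transcripts %>%
    distinct(.data$gene_id) %>%
    left_join(intr, by = "gene_id") %>%
    mutate(largest_intron = ifelse(is.na(.data$largest_intron), 0L,
                                   .data$largest_intron),
           is_host = .data$gene_id %in% host_genes) %>%
    select("gene_id", "is_host", "largest_intron")
}

#' Wilcoxon rank-sum (Mann-Whitney) comparison
#'
#' Mann-Whitney U with midrank ties. For small samples without ties
#' (`n1 + n2 <= 16`) the p-value is exact (full enumeration of
#' arrangements); otherwise the normal approximation with tie-corrected
#' variance and continuity correction is used. The reported `z` is the
#' continuity-corrected standardised U.
#'
#' @param a,b Numeric samples (non-empty).
#' @param alternative `"two_sided"`, `"a_greater"` (a shifted above b) or
#'   `"a_less"`.
#' @return A `rank_sum_result`: list with `statistic_u` (U for sample `a`),
#'   `z`, `p` (the requested alternative), `p_two_sided`, `p_one_sided`
#'   (for the directional alternative, or the smaller tail when two-sided
#'   was requested), `n1`, `n2`, `exact`.
#' @export
rank_sum_test <- function(a, b,
                          alternative = c("two_sided", "a_greater", "a_less")) {
  alternative <- match.arg(alternative)
  if (!length(a) || !length(b)) abort("both samples must be non-empty")
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1L)
  exact <- (n1 + n2 <= 16L) && !has_ties

  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 *
    ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
  cc <- sign(u - mu) * 0.5
  z <- if (sigma2 > 0) (u - mu - cc) / sqrt(sigma2) else 0

  wt_alt <- c(two_sided = "two.sided", a_greater = "greater",
              a_less = "less")
  pval <- function(alt) {
    suppressWarnings(
      wilcox.test(a, b, alternative = wt_alt[[alt]], exact = exact,
                  correct = TRUE)$p.value
    )
  }
  p_two <- min(1, pval("two_sided"))
  p_gr <- pval("a_greater")
  p_ls <- pval("a_less")
  p_one <- switch(alternative,
                  a_greater = p_gr, a_less = p_ls,
                  two_sided = min(p_gr, p_ls))
  p <- switch(alternative, two_sided = p_two, a_greater = p_gr, a_less = p_ls)
  structure(
    list(statistic_u = u, z = z, p = p, p_two_sided = p_two,
         p_one_sided = p_one, n1 = n1, n2 = n2, exact = exact,
         alternative = alternative),
    class = "rank_sum_result"
  )
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat("<rank_sum_result> U = ", x$statistic_u, " (n1 = ", x$n1, ", n2 = ",
      x$n2, ", ", if (x$exact) "exact" else "normal approximation", ")\n",
      "  ", x$alternative, " p = ", signif(x$p, 4), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.rank_sum_result <- function(x, ...) {
  tibble(statistic_u = x$statistic_u, z = x$z, p = x$p,
         p_two_sided = x$p_two_sided, p_one_sided = x$p_one_sided,
         n1 = x$n1, n2 = x$n2, exact = x$exact, alternative = x$alternative)
}

#' Compare antisense pair spans to synteny block sizes
#'
#' One-sided rank-sum test of whether the genomic extents spanned by
#' conserved antisense gene pairs are larger than conserved synteny blocks
#' in general (block sizes are the bp extents of externally computed
#' blocks, e.g. a BED file of block coordinates).
#'
#' @param pair_spans Integer vector of pair extents in bp.
#' @param block_sizes Integer vector of block extents in bp.
#' @return A `rank_sum_result` for the alternative "pair spans larger".
#' @export
span_size_comparison <- function(pair_spans, block_sizes) {
  rank_sum_test(pair_spans, block_sizes, alternative = "a_greater")
}

#' Plot largest-intron distributions for host vs non-host genes
#'
#' Violin/box comparison of log10 largest-intron length by host status,
#' excluding intron-less genes.
#'
#' @param intron_table Tibble from [largest_intron_per_gene()].
#' @return A ggplot object.
#' @export
plot_intron_comparison <- function(intron_table) {
  d <- intron_table %>%
    filter(.data$largest_intron > 0L) %>%
    mutate(group = ifelse(.data$is_host, "host genes", "non-host genes"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group,
                                  y = .data$largest_intron)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.5) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "largest intron per gene (bp)",
                  title = "Host genes carry longer introns") +
    ggplot2::theme_minimal()
}

#' Plot class counts of antisense overlaps
#'
#' @param pairs Output of [classify_antisense()].
#' @return A ggplot object.
#' @export
plot_class_counts <- function(pairs) {
  d <- count(pairs, class = factor(.data$class, levels = AS_CLASSES))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "classified overlaps",
                  title = "Antisense overlap classes") +
    ggplot2::theme_minimal()
}
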