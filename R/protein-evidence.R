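# Protein-coding evidence for antisense transcripts.
#
# The question: do ASTs carry homology hits to protein databases more (or
# less) often than random transcripts of the same length? Transcript length
# strongly confounds hit probability, so the null is built by resampling
# length-matched transcript sets: AST lengths are cut into 20 quantile bins
# (5% of ASTs each) and each resample draws, per bin, an equally sized
# sample without replacement from all transcripts in that bin's length
# range. The statistic is the number of transcripts with at least one
# orientation-correct hit passing the e-value threshold.

#' Keep only forward-orientation hits
#'
#' Stranded transcript data fixes the query orientation, so hits reported on
#' the reverse strand of the query (negative query frame) are artefacts and
#' are removed before any evidence counting.
#'
#' @param hits Tibble from [read_hit_table()]; must carry `query_frame`
#'   (read with `format = "outfmt6_frames"`).
#' @return The rows of `hits` with `query_frame > 0`.
#' @export
orientation_filter <- function(hits) {
  if (nrow(hits) && all(is.na(hits$query_frame))) {
    abort(paste0("hits carry no query frame information; re-read the table ",
                 "with format = \"outfmt6_frames\""))
  }
  filter(hits, !is.na(.data$query_frame) & .data$query_frame > 0L)
}

#' Quantile bin edges for length matching
#'
#' Breaks at the 5%, 10%, ..., 95% quantiles (order statistics) of the AST
#' lengths, giving `n_bins` bins each holding an equal share of ASTs when
#' lengths are distinct. Tied lengths collapse degenerate edges, merging the
#' affected bins (and hence their sampling pools). The outer breaks are the
#' AST length extremes, so transcripts shorter or longer than every AST fall
#' outside all bins and are never drawn into a length-matched sample.
#'
#' @param ast_lengths Integer vector of AST lengths.
#' @param n_bins Number of bins (default 20, i.e. 5% of ASTs per bin).
#' @return Numeric vector of breaks suitable for `cut(..., right = TRUE)`:
#'   `c(min - 1, inner order-statistic edges, max)`.
#' @export
length_bins <- function(ast_lengths, n_bins = 20L) {
  if (length(ast_lengths) < n_bins) {
    abort(paste0("need at least ", n_bins, " ASTs for ", n_bins,
                 " length bins; lower n_bins in the configuration"))
  }
  sorted <- sort(ast_lengths)
  k <- length(sorted)
  idx <- ceiling(seq_len(n_bins - 1L) * k / n_bins - 1e-9)
  edges <- unique(sorted[idx])
  unique(c(min(sorted) - 1, edges, max(sorted)))
}

#' Build a per-transcript protein-evidence index
#'
#' Flags every transcript in the universe that has at least one
#' forward-orientation hit at or below the e-value threshold, and records
#' its spliced length (the quantity used for length matching).
#'
#' @param a An [annotation_set()] defining the transcript universe.
#' @param hits Hit table with `query_frame` (queries are transcript ids).
#' @param evalue_max Qualifying-hit threshold (default 0.001).
#' @return Tibble `transcript_id`, `length`, `has_evidence`.
#' @export
build_evidence_index <- function(a, hits, evalue_max = 0.001) {
  ok <- orientation_filter(hits) %>% filter(.data$evalue <= evalue_max)
  a$transcripts %>%
    select("transcript_id", length = "spliced_length") %>%
    mutate(has_evidence = .data$transcript_id %in% ok$query_id)
}

#' Length-matched resampling test for protein evidence
#'
#' Compares the number of ASTs with protein evidence to the distribution of
#' the same count over `reps` random length-matched transcript sets. Within
#' one resample the draw per bin is without replacement from all universe
#' transcripts in the bin's length range (ASTs included); resamples are
#' independent. Empirical p-values use the add-one estimator
#' `(1 + #(null >= observed)) / (reps + 1)` (and symmetrically for the low
#' tail), so they are never zero.
#'
#' @param ast_ids Character vector of AST transcript ids (subset of the
#'   universe).
#' @param evidence Tibble from [build_evidence_index()] covering the
#'   universe.
#' @param reps Number of resamples (default 1000).
#' @param seed Integer seed; the whole null is reproducible from it.
#' @param n_bins Number of length bins (default 20).
#' @return An `enrichment_result`: list with `observed`, `null_counts`
#'   (length `reps`), `p_high`, `p_low`, `n_ast`, `n_universe`, `n_bins`,
#'   `reps`, `seed`.
#' @export
resampling_test <- function(ast_ids, evidence, reps = 1000L, seed = 1L,
                            n_bins = 20L) {
  stopifnot(!anyDuplicated(ast_ids))
  if (!all(ast_ids %in% evidence$transcript_id)) {
    abort("some ast_ids are not covered by the evidence index")
  }
  is_ast <- evidence$transcript_id %in% ast_ids
  breaks <- length_bins(evidence$length[is_ast], n_bins = n_bins)
  bin_all <- cut(evidence$length, breaks = breaks, labels = FALSE)
  bin_ast <- bin_all[is_ast]
  need <- tabulate(bin_ast, nbins = length(breaks) - 1L)
  pools <- split(which(!is.na(bin_all)), bin_all[!is.na(bin_all)])

  for (b in which(need > 0L)) {
    pool <- pools[[as.character(b)]]
    if (length(pool) < need[b]) {
      abort(paste0("length bin ", b, " needs ", need[b],
                   " transcripts but its pool holds only ", length(pool)))
    }
  }

  observed <- sum(evidence$has_evidence[is_ast])
  flags <- evidence$has_evidence
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  null_counts <- withr_seed({
    counts <- integer(reps)
    active <- which(need > 0L)
    pool_flags <- lapply(active, function(b) flags[pools[[as.character(b)]]])
    pool_sizes <- vapply(active, function(b) length(pools[[as.character(b)]]), 1L)
    for (r in seq_len(reps)) {
      tot <- 0L
      for (j in seq_along(active)) {
        k <- need[active[j]]
        tot <- tot + sum(pool_flags[[j]][sample.int(pool_sizes[j], k)])
      }
      counts[r] <- tot
    }
    counts
  })

  structure(
    list(observed = observed, null_counts = null_counts,
         p_high = (1 + sum(null_counts >= observed)) / (reps + 1),
         p_low = (1 + sum(null_counts <= observed)) / (reps + 1),
         n_ast = length(ast_ids), n_universe = nrow(evidence),
         n_bins = n_bins, reps = reps, seed = seed),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result> observed ", x$observed, "/", x$n_ast,
      " flagged ASTs; null mean ", round(mean(x$null_counts), 1),
      " (", x$reps, " resamples, ", x$n_bins, " length bins)\n",
      "  empirical p (high/low): ", signif(x$p_high, 4), " / ",
      signif(x$p_low, 4), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble(resample = seq_along(x$null_counts), null_count = x$null_counts)
}

#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(observed = x$observed, null_mean = mean(x$null_counts),
         null_sd = stats::sd(x$null_counts), p_high = x$p_high,
         p_low = x$p_low, n_ast = x$n_ast, n_universe = x$n_universe,
         n_bins = x$n_bins, reps = x$reps)
}

#' Plot an enrichment result
#'
#' Histogram of the resampled null counts with the observed AST count as a
#' vertical line.
#'
#' @param object An `enrichment_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$null_count)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red",
                        linewidth = 1) +
    ggplot2::labs(x = "transcripts with protein evidence (null resamples)",
                  y = "resamples",
                  title = "Observed vs length-matched resampled evidence counts",
                  subtitle = paste0("observed = ", object$observed,
                                    ", empirical p(high) = ",
                                    signif(object$p_high, 3))) +
    ggplot2::theme_minimal()
}
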