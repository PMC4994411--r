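# Host/AST expression correlation vs a random-pair null.
#
# If embedded antisense transcription regulated (or were regulated by) its
# host, host/AST pairs should be shifted towards correlated or
# anticorrelated expression relative to arbitrary gene pairs. Spearman's
# rank correlation across samples is computed per pair and the distribution
# is compared to rhos of randomly drawn gene pairs; a two-sample
# Kolmogorov-Smirnov test quantifies the (otherwise visual) comparison.

#' Spearman rank correlation
#'
#' Pearson correlation of midranks. Returns `NA` (the undefined-correlation
#' signal) when either vector is constant; callers drop such pairs and count
#' them.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (anyNA(x) || anyNA(y)) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  cor(x, y, method = "spearman")
}

expr_matrix <- function(expr) {
  m <- as.matrix(expr[, -1L, drop = FALSE])
  rownames(m) <- expr$gene_id
  if (ncol(m) < 3L) abort("need at least 3 samples for correlation")
  m
}

#' Correlations of antisense gene pairs
#'
#' One Spearman rho per evaluable (host gene, AST gene) pair. Pairs with a
#' gene absent from the matrix are skipped with a message; pairs with a
#' constant expression vector get `rho = NA` (undefined) and are counted by
#' downstream [compare_to_null()] as dropped.
#'
#' @param pairs Tibble whose first two columns are host and AST gene ids
#'   (e.g. the intronic rows of [classify_antisense()] selected down to
#'   `host_gene`, `ast_gene`).
#' @param expr Expression tibble from [read_expression()].
#' @return Tibble `host_gene`, `ast_gene`, `rho`.
#' @export
pair_correlations <- function(pairs, expr) {
  m <- expr_matrix(expr)
  pairs <- as_tibble(pairs)
  names(pairs)[1:2] <- c("host_gene", "ast_gene")
  present <- pairs$host_gene %in% rownames(m) & pairs$ast_gene %in% rownames(m)
  if (any(!present)) {
    inform(paste0("skipping ", sum(!present),
                  " pair(s) with gene(s) absent from the expression matrix"))
  }
  p <- pairs[present, c("host_gene", "ast_gene")]
  p$rho <- purrr::map2_dbl(p$host_gene, p$ast_gene,
                           function(h, a) spearman_rho(m[h, ], m[a, ]))
  p
}

#' Null distribution of rhos for random gene pairs
#'
#' Draws `reps * n_pairs` uniformly random distinct gene pairs (excluding
#' any pair in `exclude`, order-insensitively) and returns their Spearman
#' rhos. Reproducible from `seed`.
#'
#' @param expr Expression tibble from [read_expression()].
#' @param n_pairs Pairs per replicate (typically the number of antisense
#'   pairs).
#' @param reps Number of replicates (default 1).
#' @param seed Integer seed.
#' @param exclude Optional tibble of gene-id pairs to exclude (first two
#'   columns).
#' @return Numeric vector of rhos, length `reps * n_pairs` (`NA` for
#'   degenerate draws).
#' @export
random_pair_null <- function(expr, n_pairs, reps = 1L, seed = 1L,
                             exclude = NULL) {
  m <- expr_matrix(expr)
  genes <- rownames(m)
  if (length(genes) < 2L) abort("need at least 2 genes")
  banned <- character()
  if (!is.null(exclude) && nrow(exclude)) {
    e <- as_tibble(exclude)
    banned <- paste(pmin(e[[1L]], e[[2L]]), pmax(e[[1L]], e[[2L]]), sep = "\r")
  }
  n_total <- reps * n_pairs
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rhos <- numeric(n_total)
  drawn <- 0L
  while (drawn < n_total) {
    k <- (n_total - drawn) * 2L
    g1 <- genes[sample.int(length(genes), k, replace = TRUE)]
    g2 <- genes[sample.int(length(genes), k, replace = TRUE)]
    ok <- g1 != g2 &
      !paste(pmin(g1, g2), pmax(g1, g2), sep = "\r") %in% banned
    g1 <- g1[ok]; g2 <- g2[ok]
    take <- min(length(g1), n_total - drawn)
    if (take > 0L) {
      idx <- seq_len(take)
      rhos[drawn + idx] <- purrr::map2_dbl(g1[idx], g2[idx],
                                           function(a, b) spearman_rho(m[a, ], m[b, ]))
      drawn <- drawn + take
    }
  }
  rhos
}

#' Compare pair correlations to the random-pair null
#'
#' Two-sample Kolmogorov-Smirnov statistic plus a quantile table for both
#' sets. `NA` rhos (undefined correlations) are dropped and counted.
#'
#' @param pair_rhos Numeric vector of antisense-pair rhos (NAs allowed).
#' @param null_rhos Numeric vector of random-pair rhos (NAs allowed).
#' @return A `correlation_comparison`: list with `pair_rhos`, `null_rhos`,
#'   `n_dropped`, `ks_statistic`, `ks_p`, `quantiles` (tibble).
#' @export
compare_to_null <- function(pair_rhos, null_rhos) {
  n_dropped <- sum(is.na(pair_rhos))
  pair_rhos <- pair_rhos[!is.na(pair_rhos)]
  null_rhos <- null_rhos[!is.na(null_rhos)]
  if (!length(pair_rhos) || !length(null_rhos)) {
    abort("both rho sets must be non-empty after dropping NAs")
  }
  ks <- suppressWarnings(ks.test(pair_rhos, null_rhos))
  probs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  structure(
    list(pair_rhos = pair_rhos, null_rhos = null_rhos, n_dropped = n_dropped,
         ks_statistic = unname(ks$statistic), ks_p = ks$p.value,
         quantiles = tibble(
           quantile = probs,
           pairs = unname(quantile(pair_rhos, probs)),
           null = unname(quantile(null_rhos, probs))
         )),
    class = "correlation_comparison"
  )
}

#' @export
print.correlation_comparison <- function(x, ...) {
  cat("<correlation_comparison> ", length(x$pair_rhos), " pairs vs ",
      length(x$null_rhos), " null pairs (", x$n_dropped, " dropped)\n",
      "  KS D = ", signif(x$ks_statistic, 4), ", p = ", signif(x$ks_p, 4),
      "\n", sep = "")
  print(x$quantiles)
  invisible(x)
}

#' @export
tidy.correlation_comparison <- function(x, ...) {
  bind_rows(tibble(set = "pairs", rho = x$pair_rhos),
            tibble(set = "null", rho = x$null_rhos))
}

#' @export
glance.correlation_comparison <- function(x, ...) {
  tibble(n_pairs = length(x$pair_rhos), n_null = length(x$null_rhos),
         n_dropped = x$n_dropped, pair_median = stats::median(x$pair_rhos),
         null_median = stats::median(x$null_rhos),
         ks_statistic = x$ks_statistic, ks_p = x$ks_p)
}

#' Plot pair vs null rho distributions
#'
#' Overlaid densities of antisense-pair and random-pair Spearman rhos.
#'
#' @param object A `correlation_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.correlation_comparison <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$rho, colour = .data$set,
                               fill = .data$set)) +
    ggplot2::geom_density(alpha = 0.25) +
    ggplot2::xlim(-1, 1) +
    ggplot2::labs(x = "Spearman rho", y = "density",
                  title = "Antisense gene pairs vs random gene pairs",
                  subtitle = paste0("KS D = ", signif(object$ks_statistic, 3),
                                    ", p = ", signif(object$ks_p, 3))) +
    ggplot2::theme_minimal()
}
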