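# Cross-genome conservation of antisense gene pairs, and conserved
# non-coding element (CNE) candidate screening.
#
# A pair is called conserved in a target genome when, on some contig, the
# leftmost-to-rightmost extent of the host gene's homology hits (per strand)
# contains at least one passing AST hit on the opposite strand -- the
# configuration expected if the embedded antisense arrangement survived in
# that genome.

#' Per contig/strand spans of passing hits
#'
#' For each (subject contig, subject strand) with at least one hit at
#' `evalue < evalue_max`, the span from the leftmost hit start to the
#' rightmost hit end.
#'
#' @param hits Tibble from [read_hit_table()] (subjects are genome contigs).
#' @param evalue_max Strict threshold; hits with `evalue >= evalue_max` are
#'   ignored (default 0.001).
#' @return Tibble `contig`, `strand`, `start`, `end`, `n_hits`, sorted by
#'   contig then strand.
#' @export
hit_spans <- function(hits, evalue_max = 0.001) {
  hits <- filter(hits, .data$evalue < evalue_max)
  if (!nrow(hits)) {
    return(tibble(contig = character(), strand = character(),
                  start = integer(), end = integer(), n_hits = integer()))
  }
  hits %>%
    group_by(contig = .data$subject_id, strand = .data$subject_strand) %>%
    summarise(start = min(.data$subject_start), end = max(.data$subject_end),
              n_hits = n(), .groups = "drop") %>%
    arrange(.data$contig, .data$strand)
}

#' Call conservation of one antisense pair in one genome
#'
#' Conserved iff there is a contig and strand where the host hit span
#' contains at least one passing AST hit interval entirely, on the opposite
#' strand. The first satisfying contig in lexicographic order (then `+`
#' before `-`) is recorded. A genome without passing host hits yields
#' `conserved = FALSE` with `host_detected = FALSE`, so host absence can be
#' told apart from a lost antisense arrangement.
#'
#' @param host_hits,ast_hits Hit tables for the pair's host gene and AST
#'   against one target genome.
#' @param evalue_max Strict e-value threshold (default 0.001).
#' @return One-row tibble: `conserved`, `host_detected`, `supporting_contig`,
#'   `host_span_start`, `host_span_end`, `ast_hit_start`, `ast_hit_end`.
#' @export
call_pair <- function(host_hits, ast_hits, evalue_max = 0.001) {
  spans <- hit_spans(host_hits, evalue_max)
  none <- tibble(conserved = FALSE, host_detected = nrow(spans) > 0L,
                 supporting_contig = NA_character_,
                 host_span_start = NA_integer_, host_span_end = NA_integer_,
                 ast_hit_start = NA_integer_, ast_hit_end = NA_integer_)
  if (!nrow(spans)) return(none)
  ast <- filter(ast_hits, .data$evalue < evalue_max)
  if (!nrow(ast)) return(none)
  opp <- c(`+` = "-", `-` = "+")
  for (i in seq_len(nrow(spans))) {
    w <- ast %>%
      filter(.data$subject_id == spans$contig[i],
             .data$subject_strand == opp[[spans$strand[i]]],
             .data$subject_start >= spans$start[i],
             .data$subject_end <= spans$end[i]) %>%
      arrange(.data$subject_start)
    if (nrow(w)) {
      return(tibble(conserved = TRUE, host_detected = TRUE,
                    supporting_contig = spans$contig[i],
                    host_span_start = spans$start[i],
                    host_span_end = spans$end[i],
                    ast_hit_start = w$subject_start[1L],
                    ast_hit_end = w$subject_end[1L]))
    }
  }
  none
}

#' Build a pairs-by-genomes conservation matrix
#'
#' One span-containment call per (pair, genome) cell. A cell whose hit
#' tables are missing from the manifest is marked `NA` with a warning
#' (absent evidence, not absence).
#'
#' @param manifest Tibble with columns `genome_id`, `pair_id`, `role`
#'   (`"host"` or `"ast"`), and either a list-column `hits` of hit tibbles
#'   or a `path` column of `outfmt6` files (read on demand).
#' @param pairs,genomes Optional character vectors fixing row/column order;
#'   default: those present in the manifest.
#' @param evalue_max Strict e-value threshold (default 0.001).
#' @return A `conservation_matrix`: list with `calls` (long tibble of
#'   per-cell [call_pair()] rows) and `matrix` (wide tibble, `pair_id` by
#'   genome, logical).
#' @export
build_conservation_matrix <- function(manifest, pairs = NULL, genomes = NULL,
                                      evalue_max = 0.001) {
  manifest <- as_tibble(manifest)
  stopifnot(all(c("genome_id", "pair_id", "role") %in% names(manifest)))
  if (!"hits" %in% names(manifest)) {
    manifest$hits <- purrr::map(manifest$path, read_hit_table)
  }
  pairs <- pairs %||% sort(unique(manifest$pair_id))
  genomes <- genomes %||% sort(unique(manifest$genome_id))
  grid <- tidyr::expand_grid(pair_id = pairs, genome_id = genomes)
  key <- paste(manifest$genome_id, manifest$pair_id, manifest$role)
  n_missing <- 0L
  calls <- purrr::pmap_dfr(grid, function(pair_id, genome_id) {
    h <- match(paste(genome_id, pair_id, "host"), key)
    s <- match(paste(genome_id, pair_id, "ast"), key)
    if (is.na(h) || is.na(s)) {
      n_missing <<- n_missing + 1L
      return(tibble(pair_id = pair_id, genome_id = genome_id,
                    conserved = NA, host_detected = NA,
                    supporting_contig = NA_character_,
                    host_span_start = NA_integer_, host_span_end = NA_integer_,
                    ast_hit_start = NA_integer_, ast_hit_end = NA_integer_))
    }
    bind_cols(tibble(pair_id = pair_id, genome_id = genome_id),
              call_pair(manifest$hits[[h]], manifest$hits[[s]], evalue_max))
  })
  if (n_missing > 0L) {
    warn(paste0(n_missing, " (pair, genome) cell(s) lack a host or AST hit ",
                "table; marked NA"))
  }
  wide <- calls %>%
    select("pair_id", "genome_id", "conserved") %>%
    tidyr::pivot_wider(names_from = "genome_id", values_from = "conserved")
  structure(list(calls = calls, matrix = wide),
            class = "conservation_matrix")
}

#' @export
print.conservation_matrix <- function(x, ...) {
  n_cons <- sum(x$calls$conserved, na.rm = TRUE)
  cat("<conservation_matrix> ", n_distinct(x$calls$pair_id), " pairs x ",
      n_distinct(x$calls$genome_id), " genomes; ", n_cons,
      " conserved cell(s)\n", sep = "")
  invisible(x)
}

#' @export
tidy.conservation_matrix <- function(x, ...) x$calls

#' @export
glance.conservation_matrix <- function(x, ...) {
  tibble(n_pairs = n_distinct(x$calls$pair_id),
         n_genomes = n_distinct(x$calls$genome_id),
         n_conserved_cells = sum(x$calls$conserved, na.rm = TRUE),
         n_missing_cells = sum(is.na(x$calls$conserved)),
         n_pairs_conserved_somewhere =
           n_distinct(x$calls$pair_id[which(x$calls$conserved)]))
}

#' Plot a conservation matrix
#'
#' Presence/absence heat map of pairs by genomes.
#'
#' @param object A `conservation_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.conservation_matrix <- function(object, ...) {
  ggplot2::ggplot(object$calls,
                  ggplot2::aes(x = .data$genome_id, y = .data$pair_id,
                               fill = .data$conserved)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey85"),
                               na.value = "grey50") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Conservation of antisense gene pairs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Candidate regions for conserved non-coding elements
#'
#' Per contig, the complement of the union of the coding and repeat masks,
#' filtered to a minimum length (default 100 bp): the non-coding,
#' non-repetitive sequence eligible as CNE search queries.
#'
#' @param contig_lengths Tibble `contig`, `length`.
#' @param coding_mask,repeat_mask Tibbles `contig`, `start`, `end` (0-based
#'   half-open; e.g. from [read_bed()]).
#' @param min_len Minimum region length to keep (default 100).
#' @return Tibble `contig`, `start`, `end`, `length`, disjoint and sorted.
#' @export
cne_regions <- function(contig_lengths, coding_mask, repeat_mask,
                        min_len = 100L) {
  masks <- bind_rows(coding_mask[c("contig", "start", "end")],
                     repeat_mask[c("contig", "start", "end")])
  bad <- masks %>%
    inner_join(contig_lengths, by = "contig") %>%
    filter(.data$end > .data$length | .data$start < 0L)
  if (nrow(bad)) {
    abort(paste0("mask interval [", bad$start[1L], ",", bad$end[1L],
                 ") exceeds contig ", bad$contig[1L], " bounds"))
  }
  if (!all(masks$contig %in% contig_lengths$contig)) {
    abort("mask on a contig absent from contig_lengths")
  }
  purrr::pmap_dfr(contig_lengths, function(contig, length) {
    m <- filter(masks, .data$contig == !!contig)
    ir <- IRanges::reduce(IRanges::IRanges(m$start + 1L, m$end))
    free <- IRanges::gaps(ir, start = 1L, end = length)
    tibble(contig = contig,
           start = IRanges::start(free) - 1L,
           end = IRanges::end(free)) %>%
      mutate(length = .data$end - .data$start) %>%
      filter(.data$length >= min_len)
  }) %>%
    arrange(.data$contig, .data$start)
}

#' Count distinct CNE queries and subjects with passing hits
#'
#' From a BLASTN-style hit table of candidate regions against another
#' genome, the number of distinct query sequences with at least one hit at
#' `evalue < evalue_max` and the number of distinct subject sequences hit.
#'
#' @param hits Tibble from [read_hit_table()].
#' @param evalue_max Strict e-value threshold (default 0.001).
#' @return One-row tibble `n_query_sequences`, `n_subject_sequences`.
#' @export
count_cne <- function(hits, evalue_max = 0.001) {
  ok <- filter(hits, .data$evalue < evalue_max)
  tibble(n_query_sequences = n_distinct(ok$query_id),
         n_subject_sequences = n_distinct(ok$subject_id))
}
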