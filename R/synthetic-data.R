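# Synthetic data with planted ground truth.
#
# Every pipeline input can be generated with a known answer: a stranded
# annotation with planted antisense configurations of all five classes, an
# expression matrix with controlled rank correlation for the planted pairs
# (Gaussian copula), a protein-evidence hit table whose hit probability is
# logistic in transcript length with a configurable AST enrichment ratio,
# and per-genome homology hit tables realising a planted conservation
# matrix. Generators are pure functions of (config, seed): the same config
# yields byte-identical files.

#' Simulation configuration
#'
#' Defaults describe the study conditions the package is exercised under:
#' 200 background genes with planted overlap counts (intronic 20, nested 10,
#' exonic 8, utr3 6, utr5 4) echoing the dominance of the intronic class in
#' real stranded transcriptomes; log-normal exon/intron length models with a
#' heavier host-intron tail (hosts must accommodate an embedded gene, and
#' roughly 5% of hosts exceed 5 kb); 50 expression samples; a 20-genome
#' conservation screen; hit probability for protein evidence logistic in
#' length at base rate 0.3.
#'
#' @param seed Master seed; every generated artifact derives from it.
#' @param n_background_genes Number of plain (non-overlapping) genes.
#' @param class_counts Named integer vector of planted configuration counts
#'   (`intronic`, `nested`, `exonic`, `utr3`, `utr5`).
#' @param exon_length_meanlog,exon_length_sdlog Log-normal exon length model.
#' @param intron_length_meanlog,intron_length_sdlog Background intron model.
#' @param host_intron_meanlog,host_intron_sdlog Intron model for intronic
#'   host genes (applied to all their introns; the designated intron is
#'   additionally resampled until the AST fits).
#' @param mean_extra_exons Exon count per transcript is `1 + Poisson(this)`.
#' @param intergenic_min,intergenic_max Uniform intergenic gap range (bp).
#' @param contig_length Contig size before starting a new contig (bp).
#' @param n_samples Expression samples.
#' @param rho_target Target Spearman correlation for planted antisense
#'   pairs (scalar, recycled; 0 = the uncorrelated regime observed in real
#'   host/AST pairs).
#' @param expr_meanlog,expr_sdlog Log-normal expression marginals.
#' @param evidence_base_rate Protein-evidence hit probability at the
#'   logistic midpoint for non-AST transcripts.
#' @param evidence_enrichment_ratio Multiplier on the hit probability for
#'   ASTs (1 = null).
#' @param evidence_length_midpoint,evidence_length_slope Logistic
#'   length-dependence of the hit probability (on log length).
#' @param decoy_fraction Fraction of emitted evidence rows that are
#'   reverse-frame decoys (exercising the orientation filter).
#' @param n_genomes Target genomes in the conservation screen.
#' @param conservation_rate Probability a (pair, genome) cell is planted
#'   conserved when no explicit truth matrix is given.
#' @param conservation_truth Optional logical matrix (pairs x genomes).
#' @param hit_dropout Probability that an AST witness hit is dropped from
#'   the emitted conservation tables (host hits are never dropped, so
#'   recall on single-witness cells is exactly `1 - hit_dropout`).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_background_genes = 200L,
                              class_counts = c(intronic = 20L, nested = 10L,
                                               exonic = 8L, utr3 = 6L,
                                               utr5 = 4L),
                              exon_length_meanlog = log(200),
                              exon_length_sdlog = 0.6,
                              intron_length_meanlog = log(200),
                              intron_length_sdlog = 0.9,
                              host_intron_meanlog = log(2000),
                              host_intron_sdlog = 0.55,
                              mean_extra_exons = 2,
                              intergenic_min = 500L, intergenic_max = 2000L,
                              contig_length = 1e6,
                              n_samples = 50L,
                              rho_target = 0,
                              expr_meanlog = log(50), expr_sdlog = 1,
                              evidence_base_rate = 0.3,
                              evidence_enrichment_ratio = 1,
                              evidence_length_midpoint = 400,
                              evidence_length_slope = 1,
                              decoy_fraction = 0.2,
                              n_genomes = 20L,
                              conservation_rate = 0.35,
                              conservation_truth = NULL,
                              hit_dropout = 0) {
  counts <- setNames(rep(0L, length(AS_CLASSES)), AS_CLASSES)
  counts[names(class_counts)] <- as.integer(class_counts)
  if (any(counts < 0L)) abort("class counts must be >= 0")
  stopifnot(n_background_genes >= 0L, n_samples >= 3L,
            abs(rho_target) < 1, evidence_base_rate >= 0,
            evidence_base_rate <= 1, hit_dropout >= 0, hit_dropout < 1,
            decoy_fraction >= 0, decoy_fraction < 1, n_genomes >= 1L)
  structure(
    list(seed = as.integer(seed), n_background_genes = n_background_genes,
         class_counts = counts,
         exon_length_meanlog = exon_length_meanlog,
         exon_length_sdlog = exon_length_sdlog,
         intron_length_meanlog = intron_length_meanlog,
         intron_length_sdlog = intron_length_sdlog,
         host_intron_meanlog = host_intron_meanlog,
         host_intron_sdlog = host_intron_sdlog,
         mean_extra_exons = mean_extra_exons,
         intergenic_min = intergenic_min, intergenic_max = intergenic_max,
         contig_length = contig_length,
         n_samples = n_samples, rho_target = rho_target,
         expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
         evidence_base_rate = evidence_base_rate,
         evidence_enrichment_ratio = evidence_enrichment_ratio,
         evidence_length_midpoint = evidence_length_midpoint,
         evidence_length_slope = evidence_length_slope,
         decoy_fraction = decoy_fraction,
         n_genomes = n_genomes, conservation_rate = conservation_rate,
         conservation_truth = conservation_truth,
         hit_dropout = hit_dropout),
    class = "simulation_config"
  )
}

rint <- function(n, min, max) {
  if (max < min) max <- min
  as.integer(min + floor(runif(n) * (max - min + 1)))
}

draw_len <- function(n, meanlog, sdlog, lo = 50L) {
  pmax(lo, as.integer(ceiling(rlnorm(n, meanlog, sdlog))))
}

# exon coordinates (relative to 0) from exon and intron lengths
lay_exons <- function(exon_lens, intron_lens) {
  starts <- cumsum(c(0L, exon_lens[-length(exon_lens)] + intron_lens))
  tibble(start = starts, end = starts + exon_lens)
}

# draw an intron length >= need from the host model (resampling)
draw_intron_at_least <- function(need, meanlog, sdlog, lo = 30L) {
  for (i in seq_len(2000L)) {
    x <- draw_len(1L, meanlog, sdlog, lo = lo)
    if (x >= need) return(x)
  }
  abort(paste0("infeasible configuration: cannot draw an intron of length >= ",
               need, " from the host intron model"))
}

#' Simulate a stranded annotation with planted antisense configurations
#'
#' Lays out background genes and planted configurations of all five overlap
#' classes along synthetic contigs, with intergenic gaps so that no
#' unplanted opposite-strand overlap arises. Intronic hosts draw all their
#' introns from the (long-tailed) host intron model; the designated intron
#' is resampled until the embedded AST fits with margin, and the generator
#' errors before emission if the configuration is geometrically infeasible.
#'
#' @param cfg A [simulation_config()].
#' @return List with `annotation` (an [annotation_set()]) and `truth`
#'   (list: `pairs` tibble with `pair_id`, `class`, host/AST transcript and
#'   gene ids; `genes` tibble with `gene_id`, `role`, `is_host`).
#' @export
simulate_annotation <- function(cfg) {
  with_seed(cfg$seed, simulate_annotation_impl(cfg))
}

simulate_annotation_impl <- function(cfg) {
  units <- list()
  truth_pairs <- list()
  gid <- 0L
  next_gene <- function() { gid <<- gid + 1L; pad_id("g", gid) }
  tx_of <- function(g) sub("^g", "t", g)

  mk_tx <- function(gene, strand, exons, offset = 0L) {
    list(transcripts = tibble(transcript_id = tx_of(gene), gene_id = gene,
                              contig = NA_character_, strand = strand),
         exons = tibble(transcript_id = tx_of(gene),
                        start = exons$start + offset,
                        end = exons$end + offset))
  }

  bg_gene_structure <- function(host = FALSE, min_exons = 1L,
                                designated_min = 0L) {
    n_ex <- max(min_exons, 1L + rpois(1L, cfg$mean_extra_exons))
    ex_lens <- draw_len(n_ex, cfg$exon_length_meanlog, cfg$exon_length_sdlog)
    if (n_ex == 1L) return(list(exons = lay_exons(ex_lens, integer(0)),
                                designated = NA_integer_))
    if (host) {
      in_lens <- draw_len(n_ex - 1L, cfg$host_intron_meanlog,
                          cfg$host_intron_sdlog, lo = 30L)
    } else {
      in_lens <- draw_len(n_ex - 1L, cfg$intron_length_meanlog,
                          cfg$intron_length_sdlog, lo = 30L)
    }
    d <- rint(1L, 1L, n_ex - 1L)
    if (designated_min > 0L && in_lens[d] < designated_min) {
      in_lens[d] <- draw_intron_at_least(
        designated_min,
        if (host) cfg$host_intron_meanlog else cfg$intron_length_meanlog,
        if (host) cfg$host_intron_sdlog else cfg$intron_length_sdlog
      )
    }
    list(exons = lay_exons(ex_lens, in_lens), designated = d)
  }

  rand_strand <- function() sample(c("+", "-"), 1L)
  flip <- c(`+` = "-", `-` = "+")

  # --- background genes ------------------------------------------------
  for (i in seq_len(cfg$n_background_genes)) {
    g <- next_gene()
    s <- bg_gene_structure()
    units[[length(units) + 1L]] <- list(
      parts = list(mk_tx(g, rand_strand(), s$exons)),
      genes = tibble(gene_id = g, role = "background", is_host = FALSE))
  }

  # --- intronic: AST fully inside one host intron ----------------------
  for (i in seq_len(cfg$class_counts[["intronic"]])) {
    hg <- next_gene(); ag <- next_gene()
    n_ex_a <- rint(1L, 1L, 2L)
    a_ex_lens <- draw_len(n_ex_a, log(150), 0.5)
    a_in_lens <- if (n_ex_a > 1L) draw_len(n_ex_a - 1L, log(60), 0.4, lo = 30L)
                 else integer(0)
    a_exons <- lay_exons(a_ex_lens, a_in_lens)
    ast_span <- max(a_exons$end)
    s <- bg_gene_structure(host = TRUE, min_exons = 2L,
                           designated_min = ast_span + 20L)
    intr <- introns_of(s$exons)
    d <- s$designated
    off <- rint(1L, intr$start[d] + 10L,
                intr$end[d] - ast_span - 10L)
    hs <- rand_strand()
    units[[length(units) + 1L]] <- list(
      parts = list(mk_tx(hg, hs, s$exons),
                   mk_tx(ag, flip[[hs]], a_exons, offset = off)),
      genes = tibble(gene_id = c(hg, ag), role = c("host", "intronic_ast"),
                     is_host = c(TRUE, FALSE)))
    truth_pairs[[length(truth_pairs) + 1L]] <- tibble(
      class = "intronic", host_transcript = tx_of(hg), host_gene = hg,
      ast_transcript = tx_of(ag), ast_gene = ag,
      host_intron_index = d)
  }

  # --- nested: one AST exon in a host intron, AST not embedded ---------
  for (i in seq_len(cfg$class_counts[["nested"]])) {
    hg <- next_gene(); ag <- next_gene()
    repeat {
      s <- bg_gene_structure(min_exons = 2L, designated_min = 170L)
      d <- s$designated
      # the exon following the designated intron must host the AST's
      # protruding exon
      if (s$exons$end[d + 1L] - s$exons$start[d + 1L] >= 95L) break
    }
    intr <- introns_of(s$exons)
    e1_len <- rint(1L, 80L, min(150L, intr$end[d] - intr$start[d] - 20L))
    e1_start <- rint(1L, intr$start[d] + 10L, intr$end[d] - e1_len - 10L)
    e2_start <- s$exons$start[d + 1L] + 5L
    a_exons <- tibble(start = c(e1_start, e2_start),
                      end = c(e1_start + e1_len, e2_start + 80L))
    hs <- rand_strand()
    units[[length(units) + 1L]] <- list(
      parts = list(mk_tx(hg, hs, s$exons), mk_tx(ag, flip[[hs]], a_exons)),
      genes = tibble(gene_id = c(hg, ag), role = c("nested_host", "nested_ast"),
                     is_host = FALSE))
    truth_pairs[[length(truth_pairs) + 1L]] <- tibble(
      class = "nested", host_transcript = tx_of(hg), host_gene = hg,
      ast_transcript = tx_of(ag), ast_gene = ag,
      host_intron_index = NA_integer_)
  }

  # --- symmetric classes (single-exon geometries) ----------------------
  sym_unit <- function(class) {
    g1 <- next_gene(); g2 <- next_gene()   # g1 on +, g2 on -
    L1 <- rint(1L, 300L, 700L)
    if (class == "exonic") {
      L2 <- rint(1L, 80L, 150L)
      a <- rint(1L, 20L, L1 - L2 - 20L)
      p_ex <- tibble(start = 0L, end = L1)
      m_ex <- tibble(start = a, end = a + L2)
    } else if (class == "utr3") {        # convergent: + left, - right
      L2 <- rint(1L, 200L, 500L)
      ov <- rint(1L, 40L, min(L1, L2) - 40L)
      p_ex <- tibble(start = 0L, end = L1)
      m_ex <- tibble(start = L1 - ov, end = L1 - ov + L2)
    } else {                             # utr5, divergent: - left, + right
      L2 <- rint(1L, 200L, 500L)
      ov <- rint(1L, 40L, min(L1, L2) - 40L)
      m_ex <- tibble(start = 0L, end = L2)
      p_ex <- tibble(start = L2 - ov, end = L2 - ov + L1)
    }
    units[[length(units) + 1L]] <<- list(
      parts = list(mk_tx(g1, "+", p_ex), mk_tx(g2, "-", m_ex)),
      genes = tibble(gene_id = c(g1, g2), role = paste0(class, "_member"),
                     is_host = FALSE))
    truth_pairs[[length(truth_pairs) + 1L]] <<- tibble(
      class = class, host_transcript = tx_of(g1), host_gene = g1,
      ast_transcript = tx_of(g2), ast_gene = g2,
      host_intron_index = NA_integer_)
  }
  for (i in seq_len(cfg$class_counts[["exonic"]])) sym_unit("exonic")
  for (i in seq_len(cfg$class_counts[["utr3"]])) sym_unit("utr3")
  for (i in seq_len(cfg$class_counts[["utr5"]])) sym_unit("utr5")

  # --- place units on contigs ------------------------------------------
  ord <- sample.int(length(units))
  contig_i <- 1L
  cursor <- 0L
  tx_rows <- list(); ex_rows <- list()
  for (u in units[ord]) {
    gap <- rint(1L, cfg$intergenic_min, cfg$intergenic_max)
    base <- cursor + gap
    width <- max(vapply(u$parts, function(p) max(p$exons$end), 0L))
    if (base + width > cfg$contig_length && cursor > 0L) {
      contig_i <- contig_i + 1L
      cursor <- 0L
      base <- gap
    }
    ctg <- pad_id("contig_", contig_i, width = 2L)
    for (p in u$parts) {
      p$transcripts$contig <- ctg
      p$exons$start <- p$exons$start + base
      p$exons$end <- p$exons$end + base
      tx_rows[[length(tx_rows) + 1L]] <- p$transcripts
      ex_rows[[length(ex_rows) + 1L]] <- p$exons
    }
    cursor <- base + width
  }

  genes <- bind_rows(purrr::map(units, "genes"))
  pairs <- if (length(truth_pairs)) {
    bind_rows(truth_pairs) %>%
      mutate(pair_id = pad_id("pair_", row_number(), width = 3L)) %>%
      select("pair_id", dplyr::everything())
  } else {
    tibble(pair_id = character(), class = character(),
           host_transcript = character(), host_gene = character(),
           ast_transcript = character(), ast_gene = character(),
           host_intron_index = integer())
  }
  ann <- annotation_set(bind_rows(tx_rows), bind_rows(ex_rows))
  list(annotation = ann, truth = list(pairs = pairs, genes = genes))
}

#' Simulate an expression matrix with controlled pair correlation
#'
#' Planted intronic host/AST gene pairs are drawn from a Gaussian copula
#' whose parameter is chosen so the population Spearman correlation equals
#' `cfg$rho_target` (`r = 2 sin(pi * rho_s / 6)`); marginals are log-normal.
#' All other genes get independent log-normal noise.
#'
#' @param cfg A [simulation_config()].
#' @param truth Truth list from [simulate_annotation()].
#' @param annotation The matching [annotation_set()].
#' @return Tibble `gene_id` plus `cfg$n_samples` numeric sample columns.
#' @export
simulate_expression <- function(cfg, truth, annotation) {
  with_seed(cfg$seed + 1L, {
    genes <- unique(annotation$transcripts$gene_id)
    n <- cfg$n_samples
    m <- matrix(rlnorm(length(genes) * n, cfg$expr_meanlog, cfg$expr_sdlog),
                nrow = length(genes),
                dimnames = list(genes, sprintf("sample_%02d", seq_len(n))))
    pr <- filter(truth$pairs, .data$class == "intronic")
    done <- character()
    r <- 2 * sin(pi * cfg$rho_target / 6)
    for (i in seq_len(nrow(pr))) {
      h <- pr$host_gene[i]; a <- pr$ast_gene[i]
      if (h %in% done || a %in% done) next
      z1 <- rnorm(n)
      z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n)
      m[h, ] <- qlnorm(pnorm(z1), cfg$expr_meanlog, cfg$expr_sdlog)
      m[a, ] <- qlnorm(pnorm(z2), cfg$expr_meanlog, cfg$expr_sdlog)
      done <- c(done, h, a)
    }
    bind_cols(tibble(gene_id = genes), as_tibble(m))
  })
}

#' Simulate a protein-evidence hit table
#'
#' Each transcript receives a forward-frame hit with probability logistic
#' in log spliced length (base rate at the midpoint), multiplied by the
#' enrichment ratio for planted intronic ASTs. A configurable fraction of
#' the emitted rows are reverse-frame decoys, which the orientation filter
#' must remove.
#'
#' @param cfg A [simulation_config()].
#' @param truth Truth list from [simulate_annotation()].
#' @param annotation The matching [annotation_set()].
#' @return List with `hits` (tibble in [read_hit_table()] schema) and
#'   `truth` (tibble `transcript_id`, `is_ast`, `p_hit`, `has_forward_hit`).
#' @export
simulate_evidence_hits <- function(cfg, truth, annotation) {
  with_seed(cfg$seed + 2L, {
    tx <- annotation$transcripts
    ast_ids <- truth$pairs$ast_transcript[truth$pairs$class == "intronic"]
    is_ast <- tx$transcript_id %in% ast_ids
    p0 <- 2 * cfg$evidence_base_rate *
      plogis(cfg$evidence_length_slope *
               (log(tx$spliced_length) - log(cfg$evidence_length_midpoint)))
    p <- pmin(0.95, p0 * ifelse(is_ast, cfg$evidence_enrichment_ratio, 1))
    has_hit <- runif(nrow(tx)) < p
    mk_hits <- function(ids, frames) {
      n <- length(ids)
      if (!n) return(empty_hits())
      len <- tx$spliced_length[match(ids, tx$transcript_id)]
      alen <- pmax(20L, as.integer(len %/% 3 * runif(n, 0.3, 0.9)))
      tibble(query_id = ids,
             subject_id = pad_id("prot_", rint(n, 1L, 5000L), width = 5L),
             percent_identity = round(runif(n, 40, 95), 1),
             align_length = alen,
             query_start = 1L, query_end = pmin(len, alen * 3L),
             subject_start = 0L, subject_end = alen,
             subject_strand = "+",
             evalue = 10^-round(runif(n, 4, 60), 2),
             bit_score = round(alen * runif(n, 1, 2), 1),
             query_frame = frames)
    }
    fwd <- mk_hits(tx$transcript_id[has_hit],
                   rint(sum(has_hit), 1L, 3L))
    f <- cfg$decoy_fraction
    n_decoy <- if (f > 0) as.integer(round(f / (1 - f) * nrow(fwd))) else 0L
    dec <- mk_hits(tx$transcript_id[rint(n_decoy, 1L, nrow(tx))],
                   -rint(n_decoy, 1L, 3L))
    hits <- bind_rows(fwd, dec)
    hits <- hits[sample.int(nrow(hits)), ]
    list(hits = hits,
         truth = tibble(transcript_id = tx$transcript_id, is_ast = is_ast,
                        p_hit = p, has_forward_hit = has_hit))
  })
}

#' Simulate per-genome conservation hit tables
#'
#' Realises a planted pairs-by-genomes truth matrix as TBLASTN-style hit
#' tables. A conserved cell gets host hits spanning a region on one strand
#' of a contig plus a single AST witness hit inside the span on the
#' opposite strand; a non-conserved cell gets one of three failure modes
#' (no AST hits, AST hit outside the span, AST hit inside but on the same
#' strand), recorded in the truth. Each AST witness is dropped with
#' probability `cfg$hit_dropout`; host hits are never dropped, so recall on
#' conserved cells is exactly `1 - hit_dropout`.
#'
#' @param cfg A [simulation_config()].
#' @param truth Truth list from [simulate_annotation()].
#' @return List with `manifest` (tibble `genome_id`, `pair_id`, `role`,
#'   `hits` list-column) and `truth` (tibble `pair_id`, `genome_id`,
#'   `conserved`, `mode`).
#' @export
simulate_conservation_hits <- function(cfg, truth) {
  with_seed(cfg$seed + 3L, {
    pairs <- truth$pairs$pair_id[truth$pairs$class == "intronic"]
    genomes <- pad_id("genome_", seq_len(cfg$n_genomes), width = 2L)
    if (!length(pairs)) {
      return(list(manifest = tibble(genome_id = character(),
                                    pair_id = character(), role = character(),
                                    hits = list()),
                  truth = tibble(pair_id = character(), genome_id = character(),
                                 conserved = logical(),
                                 mode = character())))
    }
    tm <- cfg$conservation_truth
    if (is.null(tm)) {
      tm <- matrix(runif(length(pairs) * cfg$n_genomes) < cfg$conservation_rate,
                   nrow = length(pairs),
                   dimnames = list(pairs, genomes))
    }
    grid <- tidyr::expand_grid(pair_id = pairs, genome_id = genomes)
    grid$conserved <- tm[cbind(grid$pair_id, grid$genome_id)]
    grid$mode <- ifelse(grid$conserved, "witness",
                        sample(c("no_ast", "outside", "same_strand"),
                               nrow(grid), replace = TRUE))
    mk_row <- function(qid, ctg, start, end, strand, evalue) {
      tibble(query_id = qid, subject_id = ctg,
             percent_identity = round(runif(1L, 35, 90), 1),
             align_length = as.integer((end - start) %/% 3),
             query_start = 1L, query_end = as.integer((end - start) %/% 3),
             subject_start = as.integer(start), subject_end = as.integer(end),
             subject_strand = strand,
             evalue = evalue, bit_score = round(runif(1L, 60, 400), 1),
             query_frame = NA_integer_)
    }
    manifest <- purrr::pmap_dfr(grid, function(pair_id, genome_id, conserved,
                                               mode) {
      ctg <- paste0(genome_id, "_ctg", rint(1L, 1L, 3L))
      s <- sample(c("+", "-"), 1L)
      opp <- if (s == "+") "-" else "+"
      A <- rint(1L, 10000L, 900000L)
      W <- rint(1L, 4000L, 12000L)
      host <- bind_rows(
        mk_row(paste0(pair_id, "_host"), ctg, A, A + 300L, s,
               10^-round(runif(1L, 5, 60), 1)),
        mk_row(paste0(pair_id, "_host"), ctg,
               A + rint(1L, 800L, W - 1200L), A + rint(1L, 800L, W - 1200L) + 250L,
               s, 10^-round(runif(1L, 5, 60), 1)),
        mk_row(paste0(pair_id, "_host"), ctg, A + W - 300L, A + W, s,
               10^-round(runif(1L, 5, 60), 1))
      )
      wlen <- rint(1L, 150L, 400L)
      ast <- switch(mode,
        witness = {
          st <- rint(1L, A + 500L, A + W - 500L - wlen)
          mk_row(paste0(pair_id, "_ast"), ctg, st, st + wlen, opp,
                 10^-round(runif(1L, 5, 60), 1))
        },
        no_ast = empty_hits(),
        outside = mk_row(paste0(pair_id, "_ast"), ctg, A + W + 1000L,
                         A + W + 1000L + wlen, opp,
                         10^-round(runif(1L, 5, 60), 1)),
        same_strand = {
          st <- rint(1L, A + 500L, A + W - 500L - wlen)
          mk_row(paste0(pair_id, "_ast"), ctg, st, st + wlen, s,
                 10^-round(runif(1L, 5, 60), 1))
        })
      # a failing-e-value distractor inside the span, sometimes
      if (runif(1L) < 0.3) {
        st <- rint(1L, A + 500L, A + W - 700L)
        ast <- bind_rows(ast, mk_row(paste0(pair_id, "_ast"), ctg, st,
                                     st + 100L, opp, 0.01))
      }
      if (cfg$hit_dropout > 0 && nrow(ast)) {
        keep <- runif(nrow(ast)) >= cfg$hit_dropout
        ast <- ast[keep, ]
      }
      tibble(genome_id = genome_id, pair_id = pair_id,
             role = c("host", "ast"), hits = list(host, ast))
    })
    list(manifest = manifest, truth = as_tibble(grid))
  })
}
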