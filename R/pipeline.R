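# End-to-end orchestration: simulate a bundle of input files, then run
# classification -> protein evidence -> expression correlation ->
# conservation -> intron comparison over them, with a single JSON report.
# All stage randomness derives from one master seed through per-stage
# sub-seeds, so enabling or disabling a stage never perturbs another
# stage's draws, and a rerun with the same seed is byte-identical.

#' Write a complete synthetic input bundle to disk
#'
#' Generates the annotation, expression matrix, protein-evidence hit table
#' and per-genome conservation hit tables for one configuration and writes
#' them as plain-text files (GFF3 / TSV / tabular hits) plus a JSON truth
#' record. Re-running with the same configuration reproduces every file
#' byte for byte.
#'
#' @param cfg A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list of the written paths.
#' @export
simulate_bundle <- function(cfg, dir) {
  dir.create(file.path(dir, "conservation"), recursive = TRUE,
             showWarnings = FALSE)
  sim <- simulate_annotation(cfg)
  expr <- simulate_expression(cfg, sim$truth, sim$annotation)
  ev <- simulate_evidence_hits(cfg, sim$truth, sim$annotation)
  cons <- simulate_conservation_hits(cfg, sim$truth)

  paths <- list(
    annotation = file.path(dir, "annotation.gff3"),
    expression = file.path(dir, "expression.tsv"),
    evidence = file.path(dir, "evidence_hits.tsv"),
    manifest = file.path(dir, "conservation_manifest.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_annotation(sim$annotation, paths$annotation, dialect = "gff3")
  readr::write_tsv(expr, paths$expression, progress = FALSE)
  write_hit_table(ev$hits, paths$evidence)

  manifest <- cons$manifest
  if (nrow(manifest)) {
    by_genome <- split(manifest, manifest$genome_id)
    for (g in names(by_genome)) {
      write_hit_table(bind_rows(by_genome[[g]]$hits),
                      file.path(dir, "conservation", paste0(g, ".tsv")))
    }
    readr::write_tsv(
      manifest %>%
        mutate(query_id = paste0(.data$pair_id, "_", .data$role),
               path = file.path("conservation",
                                paste0(.data$genome_id, ".tsv"))) %>%
        select("genome_id", "pair_id", "role", "query_id", "path"),
      paths$manifest, progress = FALSE)
  }

  truth <- list(
    pairs = sim$truth$pairs,
    genes = sim$truth$genes,
    evidence = ev$truth,
    conservation = cons$truth,
    rho_target = cfg$rho_target
  )
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

read_bundle_manifest <- function(dir) {
  mpath <- file.path(dir, "conservation_manifest.tsv")
  if (!file.exists(mpath)) return(NULL)
  man <- readr::read_tsv(mpath, show_col_types = FALSE, progress = FALSE)
  tables <- lapply(unique(man$path), function(p) {
    read_hit_table(file.path(dir, p))
  })
  names(tables) <- unique(man$path)
  man$hits <- purrr::map2(man$path, man$query_id, function(p, q) {
    filter(tables[[p]], .data$query_id == q)
  })
  man
}

#' Run the full antisense analysis pipeline over an input bundle
#'
#' Executes, in dependency order, overlap classification, the
#' length-matched protein-evidence resampling test, expression correlation
#' against a random-pair null, the cross-genome conservation screen, and
#' the host/non-host largest-intron comparison, over the files written by
#' [simulate_bundle()] (or files of the same layout). A JSON report with
#' per-stage summaries and a resolved-configuration copy are written to
#' `out_dir`; no timestamps are embedded, so identical inputs and seed
#' yield a byte-identical report.
#'
#' @param bundle_dir Directory holding `annotation.gff3`, `expression.tsv`,
#'   `evidence_hits.tsv` and the conservation manifest/tables.
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed for the stochastic stages.
#' @param stages Character vector of stages to report (classification is
#'   always computed, as later stages depend on it).
#' @param reps Resamples for the protein-evidence null (default 1000).
#' @param null_pair_factor The random-pair null draws
#'   `null_pair_factor * n_pairs` gene pairs (default 50).
#' @param evalue_max Strict e-value threshold (default 0.001).
#' @param n_bins Length bins for the evidence test (default 20).
#' @return Invisibly, the report list.
#' @export
run_antisense_pipeline <- function(bundle_dir, out_dir,
                                   seed = 1L,
                                   stages = c("classify", "enrich",
                                              "correlate", "conserve",
                                              "introns"),
                                   reps = 1000L,
                                   null_pair_factor = 50L,
                                   evalue_max = 0.001,
                                   n_bins = 20L) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = seed, stages = as.list(stages))

  ann <- read_annotation(file.path(bundle_dir, "annotation.gff3"), "gff3")
  pairs <- classify_antisense(ann)
  intronic <- filter(pairs, .data$class == "intronic")

  if ("classify" %in% stages) {
    smry <- summarize_antisense(pairs)
    readr::write_tsv(pairs, file.path(out_dir, "classified_pairs.tsv"),
                     progress = FALSE)
    report$classify <- as.list(smry)
  }

  if ("enrich" %in% stages) {
    hits <- read_hit_table(file.path(bundle_dir, "evidence_hits.tsv"),
                           format = "outfmt6_frames")
    evidence <- build_evidence_index(ann, hits, evalue_max = evalue_max)
    enr <- resampling_test(unique(intronic$ast_transcript), evidence,
                           reps = reps, seed = stage_seed(seed, "enrich"),
                           n_bins = n_bins)
    readr::write_tsv(tidy(enr), file.path(out_dir, "null_counts.tsv"),
                     progress = FALSE)
    report$enrich <- as.list(glance(enr))
  }

  if ("correlate" %in% stages) {
    expr <- read_expression(file.path(bundle_dir, "expression.tsv"))
    gp <- distinct(intronic, .data$host_gene, .data$ast_gene)
    rho <- pair_correlations(gp, expr)
    nulls <- random_pair_null(expr, n_pairs = nrow(gp),
                              reps = null_pair_factor,
                              seed = stage_seed(seed, "correlate"),
                              exclude = gp)
    cmp <- compare_to_null(rho$rho, nulls)
    readr::write_tsv(rho, file.path(out_dir, "pair_rhos.tsv"),
                     progress = FALSE)
    report$correlate <- c(as.list(glance(cmp)),
                          list(quantiles = cmp$quantiles))
  }

  if ("conserve" %in% stages) {
    man <- read_bundle_manifest(bundle_dir)
    if (is.null(man)) {
      report$conserve <- list(skipped = "no conservation manifest")
    } else {
      cm <- build_conservation_matrix(man, evalue_max = evalue_max)
      readr::write_tsv(cm$matrix, file.path(out_dir, "conservation_matrix.tsv"),
                       progress = FALSE)
      readr::write_tsv(cm$calls, file.path(out_dir, "conservation_calls.tsv"),
                       progress = FALSE)
      report$conserve <- as.list(glance(cm))
    }
  }

  if ("introns" %in% stages) {
    itab <- largest_intron_per_gene(ann, host_genes = unique(intronic$host_gene))
    d <- filter(itab, .data$largest_intron > 0L)
    if (!any(d$is_host) || all(d$is_host)) {
      report$introns <- list(skipped = "need both host and non-host genes with introns")
    } else {
    rs <- rank_sum_test(d$largest_intron[d$is_host],
                        d$largest_intron[!d$is_host],
                        alternative = "a_greater")
    readr::write_tsv(itab, file.path(out_dir, "largest_introns.tsv"),
                     progress = FALSE)
    report$introns <- c(as.list(tidy(rs)),
                        list(host_median = stats::median(
                               d$largest_intron[d$is_host]),
                             nonhost_median = stats::median(
                               d$largest_intron[!d$is_host])))
    }
  }

  resolved <- list(bundle_dir = bundle_dir, seed = seed, stages = stages,
                   reps = reps, null_pair_factor = null_pair_factor,
                   evalue_max = evalue_max, n_bins = n_bins)
  jsonlite::write_json(resolved, file.path(out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
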