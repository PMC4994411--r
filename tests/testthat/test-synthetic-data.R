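# Ground-truth generators: determinism, truth consistency, planted effects.

test_that("the same configuration reproduces every bundle file byte-identically", {
  cfg <- simulation_config(seed = 101, n_background_genes = 30,
                           class_counts = c(intronic = 4, nested = 2,
                                            exonic = 1, utr3 = 1, utr5 = 1),
                           n_genomes = 3, n_samples = 10)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_bundle(cfg, d1)
  simulate_bundle(cfg, d2)
  files <- list.files(d1, recursive = TRUE)
  expect_true(length(files) > 5)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("a config with no planted classes yields no opposite-strand overlaps", {
  cfg <- simulation_config(seed = 3, n_background_genes = 40,
                           class_counts = c(intronic = 0))
  sim <- simulate_annotation(cfg)
  expect_equal(nrow(find_opposite_overlaps(sim$annotation)), 0L)
})

test_that("emitted annotation files re-read into the planted truth", {
  cfg <- simulation_config(seed = 23, n_background_genes = 25,
                           class_counts = c(intronic = 5, nested = 3,
                                            exonic = 2, utr3 = 2, utr5 = 2))
  sim <- simulate_annotation(cfg)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_annotation(sim$annotation, f, "gff3")
  re <- read_annotation(f, "gff3")
  expect_equal(re$exons, sim$annotation$exons)

  cl <- classify_antisense(re)
  truth <- sim$truth$pairs
  # every planted pair is recovered with its class, and nothing else appears
  key <- function(h, s, cls) sort(paste(h, s, cls))
  expect_equal(key(cl$host_transcript, cl$ast_transcript, cl$class),
               key(truth$host_transcript, truth$ast_transcript, truth$class))
  # intronic truth records the designated intron
  intr <- dplyr::inner_join(
    cl[cl$class == "intronic", ],
    truth[truth$class == "intronic", ],
    by = c(host_transcript = "host_transcript",
           ast_transcript = "ast_transcript"))
  expect_equal(intr$host_intron_index.x %||% intr$host_intron_index,
               intr$host_intron_index.y %||% intr$host_intron_index)
})

test_that("planted host genes carry is_host truth matching the classifier", {
  cfg <- simulation_config(seed = 29, n_background_genes = 30,
                           class_counts = c(intronic = 6, nested = 3))
  sim <- simulate_annotation(cfg)
  cl <- classify_antisense(sim$annotation)
  hosts_cl <- unique(cl$host_gene[cl$class == "intronic"])
  hosts_truth <- sim$truth$genes$gene_id[sim$truth$genes$is_host]
  expect_setequal(hosts_cl, hosts_truth)
})

test_that("copula expression hits the target rank correlation", {
  for (rho in c(0, 0.9)) {
    cfg <- simulation_config(seed = 31, n_background_genes = 5,
                             class_counts = c(intronic = 10),
                             n_samples = 500, rho_target = rho)
    sim <- simulate_annotation(cfg)
    expr <- simulate_expression(cfg, sim$truth, sim$annotation)
    pr <- dplyr::distinct(sim$truth$pairs[sim$truth$pairs$class == "intronic", ],
                          host_gene, ast_gene)
    rhos <- pair_correlations(pr, expr)$rho
    expect_lt(abs(mean(rhos) - rho), 0.05)
  }
})

test_that("expression generation is seed-deterministic", {
  cfg <- simulation_config(seed = 37, n_background_genes = 10,
                           class_counts = c(intronic = 2), n_samples = 8)
  sim <- simulate_annotation(cfg)
  e1 <- simulate_expression(cfg, sim$truth, sim$annotation)
  e2 <- simulate_expression(cfg, sim$truth, sim$annotation)
  expect_identical(e1, e2)
})

test_that("evidence hits at ratio 1 are length-only; decoys double the table at fraction 0.5", {
  cfg <- simulation_config(seed = 41, n_background_genes = 400,
                           class_counts = c(intronic = 40),
                           evidence_enrichment_ratio = 1,
                           decoy_fraction = 0.5)
  sim <- simulate_annotation(cfg)
  ev <- simulate_evidence_hits(cfg, sim$truth, sim$annotation)
  # truth hit probabilities ignore AST status at ratio 1
  expect_false(any(ev$truth$p_hit > 0.95))
  fwd <- orientation_filter(ev$hits)
  expect_equal(nrow(fwd) * 2, nrow(ev$hits), tolerance = 0.2)
  # flags in the truth match the emitted forward hits
  expect_setequal(unique(fwd$query_id),
                  ev$truth$transcript_id[ev$truth$has_forward_hit])
})

test_that("a zero base rate emits no forward hits", {
  cfg <- simulation_config(seed = 43, n_background_genes = 30,
                           class_counts = c(intronic = 2),
                           evidence_base_rate = 0, decoy_fraction = 0)
  sim <- simulate_annotation(cfg)
  ev <- simulate_evidence_hits(cfg, sim$truth, sim$annotation)
  expect_equal(nrow(ev$hits), 0L)
})

test_that("conservation tables realise the planted truth exactly at zero dropout", {
  cfg <- simulation_config(seed = 47, n_background_genes = 0,
                           class_counts = c(intronic = 8), n_genomes = 6)
  sim <- simulate_annotation(cfg)
  cons <- simulate_conservation_hits(cfg, sim$truth)
  cm <- build_conservation_matrix(cons$manifest)
  got <- dplyr::arrange(cm$calls, pair_id, genome_id)$conserved
  want <- dplyr::arrange(cons$truth, pair_id, genome_id)$conserved
  expect_identical(got, want)
})

test_that("an all-false truth matrix yields an all-false call matrix", {
  cfg <- simulation_config(seed = 53, n_background_genes = 0,
                           class_counts = c(intronic = 4), n_genomes = 4,
                           conservation_rate = 0)
  sim <- simulate_annotation(cfg)
  cons <- simulate_conservation_hits(cfg, sim$truth)
  expect_true(all(!cons$truth$conserved))
  cm <- build_conservation_matrix(cons$manifest)
  expect_true(all(cm$calls$conserved == FALSE))
})

test_that("witness dropout reduces recall to about 1 - d", {
  cfg <- simulation_config(seed = 59, n_background_genes = 0,
                           class_counts = c(intronic = 25), n_genomes = 8,
                           conservation_rate = 1, hit_dropout = 0.3)
  sim <- simulate_annotation(cfg)
  cons <- simulate_conservation_hits(cfg, sim$truth)
  cm <- build_conservation_matrix(cons$manifest)
  recall <- mean(cm$calls$conserved)
  n <- nrow(cm$calls)
  expect_lt(abs(recall - 0.7), 3 * sqrt(0.7 * 0.3 / n))
})

test_that("planted hosts' largest introns dominate background genes'", {
  cfg <- simulation_config(seed = 61, n_background_genes = 400,
                           class_counts = c(intronic = 40))
  sim <- simulate_annotation(cfg)
  itab <- largest_intron_per_gene(
    sim$annotation,
    host_genes = sim$truth$genes$gene_id[sim$truth$genes$is_host])
  d <- itab[itab$largest_intron > 0, ]
  r <- rank_sum_test(d$largest_intron[d$is_host],
                     d$largest_intron[!d$is_host], "a_greater")
  expect_lt(r$p, 1e-6)
})

test_that("an AST too long for the host intron model is an infeasibility error", {
  cfg <- simulation_config(seed = 67, n_background_genes = 0,
                           class_counts = c(intronic = 1),
                           host_intron_meanlog = log(40),
                           host_intron_sdlog = 0.01)
  expect_error(simulate_annotation(cfg), "infeasible")
})
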