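# Span-containment conservation calls and CNE region logic.

hit_row <- function(contig, start, end, strand, evalue = 1e-10, q = "q") {
  tibble::tibble(query_id = q, subject_id = contig, percent_identity = 50,
                 align_length = as.integer(end - start), query_start = 1L,
                 query_end = as.integer(end - start),
                 subject_start = as.integer(start),
                 subject_end = as.integer(end), subject_strand = strand,
                 evalue = evalue, bit_score = 100, query_frame = NA_integer_)
}

test_that("hit spans run from leftmost start to rightmost end per contig and strand", {
  h <- dplyr::bind_rows(hit_row("contigA", 999, 1200, "+"),
                        hit_row("contigA", 1499, 1600, "+"))
  sp <- hit_spans(h)
  expect_equal(nrow(sp), 1L)
  expect_equal(c(sp$start, sp$end), c(999, 1600))

  single <- hit_spans(hit_row("c", 10, 50, "-"))
  expect_equal(c(single$start, single$end), c(10, 50))
})

test_that("opposite-strand hits never merge into one span", {
  h <- dplyr::bind_rows(hit_row("c", 0, 100, "+"), hit_row("c", 200, 300, "-"))
  expect_equal(nrow(hit_spans(h)), 2L)
})

test_that("the e-value threshold is strict", {
  h <- hit_row("c", 0, 100, "+", evalue = 0.01)
  expect_equal(nrow(hit_spans(h, evalue_max = 0.001)), 0L)
  expect_equal(nrow(hit_spans(hit_row("c", 0, 100, "+", evalue = 0.001),
                              evalue_max = 0.001)), 0L)
  expect_equal(nrow(hit_spans(hit_row("c", 0, 100, "+", evalue = 0.0009),
                              evalue_max = 0.001)), 1L)
})

test_that("a pair is conserved iff an AST hit lies inside the host span on the opposite strand", {
  host <- dplyr::bind_rows(hit_row("contigA", 999, 1200, "+"),
                           hit_row("contigA", 1499, 1600, "+"))
  expect_true(call_pair(host, hit_row("contigA", 1249, 1350, "-"))$conserved)
  expect_false(call_pair(host, hit_row("contigA", 1699, 1800, "-"))$conserved)
  expect_false(call_pair(host, hit_row("contigA", 1249, 1350, "+"))$conserved)
  expect_false(call_pair(host, hit_row("contigB", 1249, 1350, "-"))$conserved)
})

test_that("host absence is reported separately from a negative call", {
  r <- call_pair(antisenser:::empty_hits(), hit_row("c", 10, 20, "-"))
  expect_false(r$conserved)
  expect_false(r$host_detected)
  r2 <- call_pair(hit_row("c", 0, 100, "+"), antisenser:::empty_hits())
  expect_false(r2$conserved)
  expect_true(r2$host_detected)
})

test_that("conservation calls match the brute-force triple-enumeration oracle", {
  set.seed(51)
  for (i in 1:300) {
    t <- random_hit_tables()
    expect_equal(call_pair(t$host, t$ast)$conserved,
                 oracle_call_pair(t$host, t$ast))
  }
})

test_that("adding a passing hit never flips a conserved call to false", {
  set.seed(52)
  for (i in 1:60) {
    s <- sample(c("+", "-"), 1)
    opp <- if (s == "+") "-" else "+"
    host <- dplyr::bind_rows(hit_row("ctgA", 0, 100, s),
                             hit_row("ctgA", 800, 1000, s))
    ast <- hit_row("ctgA", sample(150:500, 1), sample(501:750, 1), opp)
    expect_true(call_pair(host, ast)$conserved)
    extra_host <- hit_row(sample(c("ctgA", "ctgB"), 1), sample(0:900, 1),
                          sample(901:1200, 1), sample(c("+", "-"), 1))
    expect_true(call_pair(dplyr::bind_rows(host, extra_host), ast)$conserved)
    extra_ast <- hit_row(sample(c("ctgA", "ctgB"), 1), sample(0:900, 1),
                         sample(901:1200, 1), sample(c("+", "-"), 1))
    expect_true(call_pair(host, dplyr::bind_rows(ast, extra_ast))$conserved)
  }
})

test_that("the matrix builder recovers a planted truth and flags missing tables", {
  cfg <- simulation_config(seed = 19, n_background_genes = 0,
                           class_counts = c(intronic = 6), n_genomes = 5)
  sim <- simulate_annotation(cfg)
  cons <- simulate_conservation_hits(cfg, sim$truth)
  cm <- build_conservation_matrix(cons$manifest)
  got <- dplyr::arrange(cm$calls, pair_id, genome_id)
  want <- dplyr::arrange(cons$truth, pair_id, genome_id)
  expect_equal(got$conserved, want$conserved)

  # drop one cell's host table -> NA with a warning
  m2 <- cons$manifest[-1, ]
  expect_warning(cm2 <- build_conservation_matrix(m2), "lack")
  expect_equal(sum(is.na(cm2$calls$conserved)), 1L)
})

test_that("all-empty hit tables give an all-false matrix", {
  man <- tidyr::expand_grid(genome_id = c("g1", "g2"),
                            pair_id = c("p1", "p2"),
                            role = c("host", "ast"))
  man$hits <- replicate(nrow(man), antisenser:::empty_hits(), simplify = FALSE)
  cm <- build_conservation_matrix(man)
  expect_true(all(cm$calls$conserved == FALSE))
})

test_that("CNE regions are the mask complement filtered at 100 bp", {
  cl <- tibble::tibble(contig = "c1", length = 1000L)
  coding <- tibble::tibble(contig = "c1", start = 0L, end = 300L)
  reps <- tibble::tibble(contig = "c1", start = 250L, end = 400L)
  r <- cne_regions(cl, coding, reps)
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$start, r$end), c(400, 1000))

  # fully masked contig
  full <- cne_regions(cl, tibble::tibble(contig = "c1", start = 0L, end = 1000L),
                      reps[0, ])
  expect_equal(nrow(full), 0L)

  # 99 bp gap excluded at the default minimum, kept at 99
  cl2 <- tibble::tibble(contig = "c1", length = 499L)
  m <- tibble::tibble(contig = "c1", start = c(0L, 499L - 200L),
                      end = c(200L, 499L))
  expect_equal(nrow(cne_regions(cl2, m, m[0, ])), 0L)
  expect_equal(nrow(cne_regions(cl2, m, m[0, ], min_len = 99L)), 1L)
})

test_that("a mask interval outside contig bounds is an error", {
  cl <- tibble::tibble(contig = "c1", length = 100L)
  no_mask <- tibble::tibble(contig = character(), start = integer(),
                            end = integer())
  expect_error(cne_regions(cl, tibble::tibble(contig = "c1", start = 50L,
                                              end = 150L), no_mask),
               "exceeds")
})

test_that("CNE complement matches the per-base oracle and tiles each contig", {
  set.seed(61)
  for (i in 1:60) {
    len <- sample(200:800, 1)
    n_mask <- sample(0:6, 1)
    s <- sample(0:(len - 10), n_mask, replace = TRUE)
    masks <- tibble::tibble(contig = "c", start = s,
                            end = pmin(len, s + sample(10:200, max(1, n_mask),
                                                       replace = TRUE)[seq_len(n_mask)]))
    min_len <- sample(c(1, 50, 100), 1)
    got <- cne_regions(tibble::tibble(contig = "c", length = len),
                       masks, masks[0, ], min_len = min_len)
    want <- oracle_cne(len, masks, min_len)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    # disjoint, sorted
    if (nrow(got) > 1) expect_true(all(diff(got$start) > 0))
  }
})

test_that("CNE counting reports distinct passing queries and subjects", {
  h <- dplyr::bind_rows(
    hit_row("s1", 0, 50, "+", q = "q1"), hit_row("s1", 60, 90, "+", q = "q1"),
    hit_row("s1", 0, 50, "+", q = "q2"))
  cc <- count_cne(h)
  expect_equal(cc$n_query_sequences, 2L)
  expect_equal(cc$n_subject_sequences, 1L)
  none <- count_cne(hit_row("s1", 0, 50, "+", evalue = 0.5))
  expect_equal(none$n_query_sequences, 0L)
  expect_equal(none$n_subject_sequences, 0L)
})
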