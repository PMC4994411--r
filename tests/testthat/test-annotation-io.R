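# Coordinate conventions, intron derivation, file round trips, hit parsing.

test_that("GFF3 1-based closed coordinates map to 0-based half-open exons and introns", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\ttranscript\t101\t400\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tsrc\texon\t101\t200\t.\t+\t.\tParent=t1",
    "chr1\tsrc\texon\t301\t400\t.\t+\t.\tParent=t1"
  ), f)
  a <- read_annotation(f, "gff3")
  expect_equal(a$exons$start, c(100, 300))
  expect_equal(a$exons$end, c(200, 400))
  intr <- derive_introns(a)
  expect_equal(nrow(intr), 1L)
  expect_equal(c(intr$start, intr$end, intr$length), c(200, 300, 100))
})

test_that("intron derivation: gaps between sorted exons; single exon gives none", {
  a <- make_annotation(
    list(id = "t1", strand = "+", exons = list(c(0, 100), c(500, 600))),
    list(id = "t2", strand = "+", exons = list(c(0, 100))),
    list(id = "t3", strand = "-", exons = list(c(0, 10), c(20, 30), c(40, 50)))
  )
  intr <- derive_introns(a)
  expect_equal(intr$start[intr$transcript_id == "t1"], 100)
  expect_equal(intr$end[intr$transcript_id == "t1"], 500)
  expect_false("t2" %in% intr$transcript_id)
  expect_equal(intr$start[intr$transcript_id == "t3"], c(10, 30))
  expect_equal(intr$end[intr$transcript_id == "t3"], c(20, 40))
})

test_that("exon plus intron lengths tile the span for random annotations", {
  set.seed(42)
  for (i in 1:20) {
    a <- random_annotation()
    sp <- transcript_spans(a)
    ex_len <- tapply(a$exons$end - a$exons$start, a$exons$transcript_id, sum)
    intr <- derive_introns(a)
    in_len <- tapply(intr$length, intr$transcript_id, sum)
    for (t in sp$transcript_id) {
      expect_equal(unname(ex_len[t]) + unname(if (t %in% names(in_len)) in_len[t] else 0),
                   sp$end[sp$transcript_id == t] - sp$start[sp$transcript_id == t])
    }
  }
})

test_that("GFF3 and GTF round trips reproduce the in-memory model", {
  a <- make_annotation(
    list(id = "t1", gene = "g1", strand = "+",
         exons = list(c(100, 200), c(300, 400)), cds = list(c(150, 200))),
    list(id = "t2", gene = "g2", strand = "-", exons = list(c(500, 800)))
  )
  for (dialect in c("gff3", "gtf")) {
    f <- withr::local_tempfile(fileext = paste0(".", dialect))
    write_annotation(a, f, dialect)
    b <- read_annotation(f, dialect)
    expect_equal(b$transcripts, a$transcripts)
    expect_equal(b$exons, a$exons)
    expect_equal(b$cds, a$cds)
  }
})

test_that("the two dialects encode the identical model identically", {
  a <- make_annotation(
    list(id = "t1", gene = "g1", strand = "+",
         exons = list(c(100, 200), c(300, 400))))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_annotation(a, f1, "gff3")
  write_annotation(a, f2, "gtf")
  expect_equal(read_annotation(f1, "gff3"), read_annotation(f2, "gtf"))
})

test_that("empty annotation file yields an empty set without error", {
  f <- withr::local_tempfile()
  writeLines("##gff-version 3", f)
  a <- read_annotation(f, "gff3")
  expect_s3_class(a, "annotation_set")
  expect_equal(nrow(a$transcripts), 0L)
})

test_that("malformed parent linkage is a parse error naming the line", {
  f <- withr::local_tempfile()
  writeLines(c(
    "chr1\tsrc\ttranscript\t1\t100\t.\t+\t.\tID=t1",
    "chr1\tsrc\texon\t1\t100\t.\t+\t.\tParent=missing_tx"
  ), f)
  expect_error(read_annotation(f, "gff3"), "line 2",
               class = "antisenser_parse_error")
})

test_that("exon on a different contig/strand rejects its transcript with a warning", {
  f <- withr::local_tempfile()
  writeLines(c(
    "chr1\tsrc\ttranscript\t1\t100\t.\t+\t.\tID=t1",
    "chr2\tsrc\texon\t1\t100\t.\t+\t.\tParent=t1",
    "chr1\tsrc\ttranscript\t1\t100\t.\t-\t.\tID=t2",
    "chr1\tsrc\texon\t1\t100\t.\t-\t.\tParent=t2"
  ), f)
  expect_warning(a <- read_annotation(f, "gff3"), "different contig")
  expect_equal(a$transcripts$transcript_id, "t2")
})

test_that("unstranded transcripts are rejected with a warning", {
  expect_warning(
    a <- annotation_set(
      tibble::tibble(transcript_id = c("t1", "t2"), gene_id = c("g1", "g2"),
                     contig = "c", strand = c(".", "+")),
      tibble::tibble(transcript_id = c("t1", "t2"), start = 0L, end = 10L)),
    "unstranded")
  expect_equal(a$transcripts$transcript_id, "t2")
})

test_that("overlapping exons within a transcript are merged with a warning", {
  expect_warning(
    a <- annotation_set(
      tibble::tibble(transcript_id = "t1", gene_id = "g1",
                     contig = "c", strand = "+"),
      tibble::tibble(transcript_id = "t1",
                     start = c(0L, 50L, 200L), end = c(100L, 120L, 300L))),
    "merged")
  expect_equal(a$exons$start, c(0, 200))
  expect_equal(a$exons$end, c(120, 300))
})

test_that("hit table parsing: subject strand inferred from coordinate inversion", {
  f <- withr::local_tempfile()
  writeLines(c(
    "q1\ts1\t90.0\t100\t5\t1\t1\t100\t1200\t1000\t1e-20\t180",
    "q2\ts1\t80.0\t50\t2\t0\t1\t50\t500\t700\t1e-10\t90"
  ), f)
  h <- read_hit_table(f, "outfmt6")
  expect_equal(h$subject_start[1], 999)
  expect_equal(h$subject_end[1], 1200)
  expect_equal(h$subject_strand, c("-", "+"))
  expect_true(all(is.na(h$query_frame)))
})

test_that("frames dialect retains the query frame; plain dialect has none", {
  f <- withr::local_tempfile()
  writeLines(c(
    "q1\ts1\t90.0\t100\t5\t1\t1\t100\t10\t300\t1e-20\t180\t-2\t1",
    "q2\ts1\t90.0\t100\t5\t1\t1\t100\t10\t300\t1e-20\t180\t3\t1"
  ), f)
  h <- read_hit_table(f, "outfmt6_frames")
  expect_equal(h$query_frame, c(-2L, 3L))
})

test_that("non-numeric hit coordinates are a parse error with a line number", {
  f <- withr::local_tempfile()
  writeLines(c(
    "q1\ts1\t90.0\t100\t5\t1\t1\t100\t10\t300\t1e-20\t180",
    "q2\ts1\t90.0\t100\t5\t1\t1\t100\tXX\t300\t1e-10\t90"
  ), f)
  expect_error(read_hit_table(f, "outfmt6"), "line 2",
               class = "antisenser_parse_error")
})

test_that("hit tables round-trip through write_hit_table", {
  h <- tibble::tibble(
    query_id = c("q1", "q2"), subject_id = "s1",
    percent_identity = c(90, 80.5), align_length = c(100L, 55L),
    query_start = 1L, query_end = c(100L, 55L),
    subject_start = c(999L, 499L), subject_end = c(1200L, 700L),
    subject_strand = c("-", "+"), evalue = c(1e-20, 1e-10),
    bit_score = c(180, 90.5), query_frame = c(2L, -1L))
  f <- withr::local_tempfile()
  write_hit_table(h, f)
  h2 <- read_hit_table(f, "outfmt6_frames")
  expect_equal(h2[names(h2) != "query_frame"],
               h[names(h) != "query_frame"],
               ignore_attr = TRUE)
  expect_equal(h2$query_frame, h$query_frame)
})

test_that("overlap query returns exactly the transcripts a brute-force scan finds", {
  set.seed(7)
  for (i in 1:25) {
    a <- random_annotation(n_genes = 10)
    got <- find_opposite_overlaps(a)
    want <- oracle_overlaps(a)
    key_got <- sort(paste(pmin(got$transcript_plus, got$transcript_minus),
                          pmax(got$transcript_plus, got$transcript_minus)))
    key_want <- sort(vapply(want, function(p) {
      paste(min(p), max(p))
    }, ""))
    expect_equal(key_got, key_want)
  }
})

test_that("abutting half-open spans on opposite strands do not overlap", {
  a <- make_annotation(
    list(id = "t1", strand = "+", exons = list(c(0, 100))),
    list(id = "t2", strand = "-", exons = list(c(100, 200))))
  expect_equal(nrow(find_opposite_overlaps(a)), 0L)
})

test_that("BED intervals pass through as 0-based half-open", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t0\t300\tfeat1\t0\t+", "chr1\t250\t400\tfeat2\t0\t-"), f)
  b <- read_bed(f)
  expect_equal(b$start, c(0, 250))
  expect_equal(b$end, c(300, 400))
  expect_equal(b$strand, c("+", "-"))
})
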