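# Annotation and hit-table I/O.
#
# Internal coordinates are ALWAYS 0-based half-open [start, end); GFF/GTF files
# are 1-based closed and converted on the way in/out. BED is already 0-based
# half-open and passes through unchanged.

#' Build an annotation set from transcript and exon tables
#'
#' The in-memory representation of a stranded genome annotation: a table of
#' transcripts plus a table of exons (and optionally CDS parts), all in
#' 0-based half-open coordinates. Exons are sorted per transcript and
#' touching/overlapping exons (corrupt input) are merged with a warning.
#' Transcripts without `+`/`-` strand are rejected with a warning, as is any
#' transcript whose CDS falls outside its exons: the downstream analysis is
#' strand-aware throughout.
#'
#' @param transcripts Tibble with columns `transcript_id`, `gene_id`,
#'   `contig`, `strand`.
#' @param exons Tibble with columns `transcript_id`, `start`, `end`
#'   (0-based half-open).
#' @param cds Optional tibble like `exons` for coding parts.
#' @return An `annotation_set`: a list with tibbles `transcripts` (augmented
#'   with `span_start`, `span_end`, `n_exons`, `spliced_length`), `exons`
#'   (with `exon_rank` in genome order) and `cds`.
#' @examples
#' a <- annotation_set(
#'   tibble::tibble(transcript_id = "t1", gene_id = "g1",
#'                  contig = "chrI", strand = "+"),
#'   tibble::tibble(transcript_id = "t1", start = c(100, 300), end = c(200, 400))
#' )
#' derive_introns(a)
#' @export
annotation_set <- function(transcripts, exons, cds = NULL) {
  transcripts <- as_tibble(transcripts)
  exons <- as_tibble(exons)
  cds <- if (is.null(cds)) {
    tibble(transcript_id = character(), start = integer(), end = integer())
  } else {
    as_tibble(cds)
  }
  stopifnot(
    all(c("transcript_id", "gene_id", "contig", "strand") %in% names(transcripts)),
    all(c("transcript_id", "start", "end") %in% names(exons))
  )
  if (anyDuplicated(transcripts$transcript_id)) {
    abort("duplicate transcript_id in annotation", class = "antisenser_parse_error")
  }
  bad_strand <- transcripts$transcript_id[!transcripts$strand %in% c("+", "-")]
  if (length(bad_strand)) {
    warn(paste0("rejecting ", length(bad_strand),
                " unstranded/invalid-strand transcript(s): ",
                paste(head(bad_strand, 5L), collapse = ", ")))
    transcripts <- filter(transcripts, .data$strand %in% c("+", "-"))
  }
  exons <- semi_join(exons, transcripts, by = "transcript_id")
  cds <- semi_join(cds, transcripts, by = "transcript_id")
  if (any(exons$start < 0L) || any(exons$end <= exons$start)) {
    abort("exon with start < 0 or end <= start", class = "antisenser_parse_error")
  }

  if (!nrow(exons)) {
    return(structure(
      list(transcripts = tibble(transcript_id = character(),
                                gene_id = character(), contig = character(),
                                strand = character(), span_start = integer(),
                                span_end = integer(), n_exons = integer(),
                                spliced_length = integer()),
           exons = tibble(transcript_id = character(), start = integer(),
                          end = integer(), exon_rank = integer()),
           cds = tibble(transcript_id = character(), start = integer(),
                        end = integer())),
      class = "annotation_set"))
  }

  exons <- arrange(exons, .data$transcript_id, .data$start, .data$end)
  merged <- merge_touching(exons)
  if (nrow(merged) < nrow(exons)) {
    warn("merged overlapping/touching exons within a transcript (corrupt input)")
  }
  exons <- merged %>%
    group_by(.data$transcript_id) %>%
    mutate(exon_rank = row_number()) %>%
    ungroup()

  no_exon <- setdiff(transcripts$transcript_id, unique(exons$transcript_id))
  if (length(no_exon)) {
    warn(paste0("rejecting ", length(no_exon), " transcript(s) without exons"))
    transcripts <- filter(transcripts, !.data$transcript_id %in% no_exon)
  }

  if (nrow(cds)) {
    cds <- arrange(cds, .data$transcript_id, .data$start)
    ok <- cds_within_exons(cds, exons)
    if (!all(ok)) {
      bad <- unique(cds$transcript_id[!ok])
      warn(paste0("rejecting ", length(bad),
                  " transcript(s) with CDS outside exons: ",
                  paste(head(bad, 5L), collapse = ", ")))
      transcripts <- filter(transcripts, !.data$transcript_id %in% bad)
      exons <- filter(exons, !.data$transcript_id %in% bad)
      cds <- filter(cds, !.data$transcript_id %in% bad)
    }
  }

  span <- exons %>%
    group_by(.data$transcript_id) %>%
    summarise(span_start = min(.data$start), span_end = max(.data$end),
              n_exons = n(), spliced_length = sum(.data$end - .data$start),
              .groups = "drop")
  transcripts <- transcripts %>%
    select("transcript_id", "gene_id", "contig", "strand") %>%
    inner_join(span, by = "transcript_id") %>%
    arrange(.data$contig, .data$span_start, .data$transcript_id)

  structure(
    list(transcripts = transcripts,
         exons = select(exons, "transcript_id", "start", "end", "exon_rank"),
         cds = select(cds, "transcript_id", "start", "end")),
    class = "annotation_set"
  )
}

# merge touching/overlapping intervals within each transcript (input sorted)
merge_touching <- function(exons) {
  exons %>%
    group_by(.data$transcript_id) %>%
    mutate(grp = cumsum(.data$start > lag(cummax(.data$end), default = -1L))) %>%
    group_by(.data$transcript_id, .data$grp) %>%
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") %>%
    select(-"grp") %>%
    arrange(.data$transcript_id, .data$start)
}

# TRUE for each CDS part contained in one exon of its transcript
cds_within_exons <- function(cds, exons) {
  m <- left_join(
    mutate(cds, .row = row_number()),
    exons,
    by = join_by(transcript_id, within(start, end, start, end)),
    suffix = c("", ".exon")
  )
  !is.na(m$start.exon[match(seq_len(nrow(cds)), m$.row)])
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("<annotation_set> ", nrow(x$transcripts), " transcripts, ",
      n_distinct(x$transcripts$gene_id), " genes, ",
      nrow(x$exons), " exons",
      if (nrow(x$cds)) paste0(", ", nrow(x$cds), " CDS parts") else "",
      "\n", sep = "")
  invisible(x)
}

#' Transcript spans as a tibble
#'
#' @param a An [annotation_set()].
#' @return Tibble with one row per transcript: `transcript_id`, `gene_id`,
#'   `contig`, `strand`, `start`, `end` (genomic span, 0-based half-open).
#' @export
transcript_spans <- function(a) {
  a$transcripts %>%
    select("transcript_id", "gene_id", "contig", "strand",
           start = "span_start", end = "span_end")
}

#' Derive introns from exon structure
#'
#' Introns are the gaps between consecutive exons of a transcript;
#' a single-exon transcript has none. For every transcript the exon and
#' intron lengths tile the genomic span exactly.
#'
#' @param a An [annotation_set()].
#' @param transcript_id Optional character vector restricting to some
#'   transcripts.
#' @return Tibble `transcript_id`, `intron_index` (1-based, genome order),
#'   `start`, `end`, `length`.
#' @export
derive_introns <- function(a, transcript_id = NULL) {
  ex <- a$exons
  if (!is.null(transcript_id)) ex <- filter(ex, .data$transcript_id %in% !!transcript_id)
  ex %>%
    group_by(.data$transcript_id) %>%
    filter(n() > 1L) %>%
    dplyr::reframe(intron_start = .data$end[-n()],
                   intron_end = .data$start[-1L],
                   intron_index = seq_len(n() - 1L)) %>%
    mutate(length = .data$intron_end - .data$intron_start) %>%
    select("transcript_id", "intron_index", start = "intron_start",
           end = "intron_end", "length")
}

gff_attr <- function(attrs, key, dialect) {
  if (dialect == "gff3") {
    m <- stringr::str_match(attrs, paste0("(?:^|;)\\s*", key, "=([^;]+)"))[, 2L]
  } else {
    m <- stringr::str_match(attrs, paste0('(?:^|;)\\s*', key, '\\s+"([^"]*)"'))[, 2L]
  }
  m
}

parse_tabular_lines <- function(path, n_min) {
  lines <- readr::read_lines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  list(lines = lines[keep], lineno = which(keep))
}

#' Read a genome annotation (GFF3 or GTF)
#'
#' Reads transcript/mRNA, exon and CDS features into an [annotation_set()],
#' converting the file's 1-based closed coordinates to internal 0-based
#' half-open. Parent linkage (GFF3 `Parent=` / GTF `transcript_id`) is
#' required for exon and CDS rows; a malformed or dangling link is a parse
#' error naming the offending line. An exon on a different contig or strand
#' than its transcript causes that transcript to be rejected with a warning.
#' An empty file yields an empty annotation set.
#'
#' @param path Path to the annotation file.
#' @param dialect `"gff3"` or `"gtf"`.
#' @return An [annotation_set()].
#' @export
read_annotation <- function(path, dialect = c("gff3", "gtf")) {
  dialect <- match.arg(dialect)
  parsed <- parse_tabular_lines(path)
  if (!length(parsed$lines)) {
    return(annotation_set(
      tibble(transcript_id = character(), gene_id = character(),
             contig = character(), strand = character()),
      tibble(transcript_id = character(), start = integer(), end = integer())
    ))
  }
  fields <- stringr::str_split(parsed$lines, "\t")
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    abort(paste0("expected 9 tab-separated columns at line ",
                 parsed$lineno[which(nf != 9L)[1L]]),
          class = "antisenser_parse_error")
  }
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  start1 <- suppressWarnings(as.integer(m[, 4L]))
  end1 <- suppressWarnings(as.integer(m[, 5L]))
  if (anyNA(start1) || anyNA(end1)) {
    abort(paste0("non-numeric coordinate at line ",
                 parsed$lineno[which(is.na(start1) | is.na(end1))[1L]]),
          class = "antisenser_parse_error")
  }
  feat <- tibble(
    contig = m[, 1L], type = m[, 3L],
    start = start1 - 1L, end = end1,     # 1-based closed -> 0-based half-open
    strand = m[, 7L], attrs = m[, 9L], lineno = parsed$lineno
  )

  is_tx <- feat$type %in% c("mRNA", "transcript")
  is_part <- feat$type %in% c("exon", "CDS")

  if (dialect == "gff3") {
    tx_id <- gff_attr(feat$attrs, "ID", dialect)
    tx_gene <- gff_attr(feat$attrs, "Parent", dialect)
    part_parent <- gff_attr(feat$attrs, "Parent", dialect)
  } else {
    tx_id <- gff_attr(feat$attrs, "transcript_id", dialect)
    tx_gene <- gff_attr(feat$attrs, "gene_id", dialect)
    part_parent <- tx_id
  }

  tx <- feat[is_tx, ]
  tx$transcript_id <- tx_id[is_tx]
  tx$gene_id <- tx_gene[is_tx]
  if (anyNA(tx$transcript_id)) {
    abort(paste0("transcript record without ",
                 if (dialect == "gff3") "ID" else "transcript_id",
                 " at line ", tx$lineno[which(is.na(tx$transcript_id))[1L]]),
          class = "antisenser_parse_error")
  }
  tx$gene_id <- ifelse(is.na(tx$gene_id), tx$transcript_id, tx$gene_id)

  parts <- feat[is_part, ]
  parts$parent <- part_parent[is_part]
  if (anyNA(parts$parent)) {
    abort(paste0("exon/CDS record without parent linkage at line ",
                 parts$lineno[which(is.na(parts$parent))[1L]]),
          class = "antisenser_parse_error")
  }
  # GFF3 allows multi-parent exons: duplicate the row per parent
  if (dialect == "gff3" && any(grepl(",", parts$parent, fixed = TRUE))) {
    parts <- tidyr::separate_rows(parts, "parent", sep = ",")
  }

  # transcripts implied only by exon rows (common in GTF)
  implied <- parts %>%
    filter(!.data$parent %in% tx$transcript_id)
  if (nrow(implied)) {
    if (dialect == "gff3") {
      abort(paste0("exon/CDS with unknown Parent '", implied$parent[1L],
                   "' at line ", implied$lineno[1L]),
            class = "antisenser_parse_error")
    }
    extra <- implied %>%
      group_by(transcript_id = .data$parent) %>%
      summarise(contig = first(.data$contig), strand = first(.data$strand),
                gene_id = first(gff_attr(.data$attrs, "gene_id", "gtf")),
                .groups = "drop") %>%
      mutate(gene_id = ifelse(is.na(.data$gene_id), .data$transcript_id,
                              .data$gene_id))
    tx <- bind_rows(select(tx, "transcript_id", "gene_id", "contig", "strand"),
                    extra)
  }
  tx <- distinct(as_tibble(tx)[, c("transcript_id", "gene_id", "contig", "strand")])

  # exon on wrong contig/strand -> reject the whole transcript, with a warning
  chk <- parts %>%
    inner_join(tx, by = c(parent = "transcript_id"),
               suffix = c("", ".tx")) %>%
    filter(.data$contig != .data$contig.tx | .data$strand != .data$strand.tx)
  if (nrow(chk)) {
    bad <- unique(chk$parent)
    warn(paste0("rejecting ", length(bad),
                " transcript(s) with exons on a different contig/strand: ",
                paste(head(bad, 5L), collapse = ", ")))
    tx <- filter(tx, !.data$transcript_id %in% bad)
    parts <- filter(parts, !.data$parent %in% bad)
  }

  exons <- parts %>%
    filter(.data$type == "exon") %>%
    select(transcript_id = "parent", "start", "end")
  cds <- parts %>%
    filter(.data$type == "CDS") %>%
    select(transcript_id = "parent", "start", "end")
  annotation_set(tx, exons, if (nrow(cds)) cds else NULL)
}

#' Write a genome annotation (GFF3 or GTF)
#'
#' Inverse of [read_annotation()]: internal 0-based half-open coordinates are
#' written back as 1-based closed. Reading the written file recovers the same
#' annotation set (round trip).
#'
#' @param a An [annotation_set()].
#' @param path Output path.
#' @param dialect `"gff3"` or `"gtf"`.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(a, path, dialect = c("gff3", "gtf")) {
  dialect <- match.arg(dialect)
  tx <- a$transcripts
  header <- if (dialect == "gff3") "##gff-version 3" else
    "#!antisenser GTF export"
  row_of <- function(contig, type, start, end, strand, attrs) {
    paste(contig, "antisenser", type, start + 1L, end, ".", strand, ".", attrs,
          sep = "\t")
  }
  if (dialect == "gff3") {
    tx_rows <- row_of(tx$contig, "transcript", tx$span_start, tx$span_end,
                      tx$strand,
                      paste0("ID=", tx$transcript_id, ";Parent=", tx$gene_id))
    attr_of <- function(parent) paste0("Parent=", parent)
  } else {
    attrs_tx <- paste0('gene_id "', tx$gene_id, '"; transcript_id "',
                       tx$transcript_id, '";')
    tx_rows <- row_of(tx$contig, "transcript", tx$span_start, tx$span_end,
                      tx$strand, attrs_tx)
    gene_of <- setNames(tx$gene_id, tx$transcript_id)
    attr_of <- function(parent) {
      paste0('gene_id "', gene_of[parent], '"; transcript_id "', parent, '";')
    }
  }
  part_rows <- function(tbl, type) {
    if (!nrow(tbl)) return(character())
    info <- tx[match(tbl$transcript_id, tx$transcript_id), ]
    row_of(info$contig, type, tbl$start, tbl$end, info$strand,
           attr_of(tbl$transcript_id))
  }
  # order: each transcript row followed by its exons/CDS, in transcript order
  ex <- part_rows(a$exons, "exon")
  cd <- part_rows(a$cds, "CDS")
  ord <- order(match(c(a$exons$transcript_id, a$cds$transcript_id),
                     tx$transcript_id))
  body <- split(c(ex, cd)[ord],
                match(c(a$exons$transcript_id, a$cds$transcript_id),
                      tx$transcript_id)[ord])
  lines <- c(header,
             unlist(purrr::map2(tx_rows, seq_len(nrow(tx)), function(r, i) {
               c(r, body[[as.character(i)]] %||% character())
             }), use.names = FALSE))
  readr::write_lines(lines, path)
  invisible(path)
}

blast_cols <- c("query_id", "subject_id", "percent_identity", "align_length",
                "mismatches", "gap_opens", "query_start", "query_end",
                "subject_start_raw", "subject_end_raw", "evalue", "bit_score")

#' Read a BLAST-style tabular hit file
#'
#' Parses the standard 12-column tabular output (`outfmt 6`:
#' qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore), or the frames dialect with `qframe` (and optionally
#' `sframe`) appended. Subject coordinates are normalised to a 0-based
#' half-open interval with an explicit strand flag: the subject strand is
#' `-` exactly when the printed `sstart > send`. Query coordinates are kept
#' 1-based as printed; a negative `query_frame` marks a reverse-strand query
#' orientation.
#'
#' @param path Path to the tab-separated hit file (`#` comment lines allowed).
#' @param format `"outfmt6"` (12 columns) or `"outfmt6_frames"` (13-14
#'   columns, frame(s) appended).
#' @return Tibble with columns `query_id`, `subject_id`, `percent_identity`,
#'   `align_length`, `query_start`, `query_end`, `subject_start`,
#'   `subject_end` (0-based half-open, `start < end`), `subject_strand`,
#'   `evalue`, `bit_score`, `query_frame` (`NA` under plain `outfmt6`).
#' @export
read_hit_table <- function(path, format = c("outfmt6", "outfmt6_frames")) {
  format <- match.arg(format)
  parsed <- parse_tabular_lines(path)
  n_expect <- if (format == "outfmt6") 12L else c(13L, 14L)
  if (!length(parsed$lines)) return(empty_hits())
  fields <- stringr::str_split(parsed$lines, "\t")
  nf <- lengths(fields)
  if (any(!nf %in% n_expect)) {
    abort(paste0("expected ", paste(n_expect, collapse = " or "),
                 " columns at line ", parsed$lineno[which(!nf %in% n_expect)[1L]]),
          class = "antisenser_parse_error")
  }
  m <- t(vapply(fields, function(f) f[seq_len(min(nf))], character(min(nf))))
  num <- function(col, what, integerish = FALSE) {
    x <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(x)) {
      abort(paste0("non-numeric ", what, " at line ",
                   parsed$lineno[which(is.na(x))[1L]]),
            class = "antisenser_parse_error")
    }
    if (integerish) as.integer(x) else x
  }
  sstart <- num(9L, "subject start", TRUE)
  send <- num(10L, "subject end", TRUE)
  qframe <- if (format == "outfmt6_frames") num(13L, "query frame", TRUE)
            else rep(NA_integer_, nrow(m))
  tibble(
    query_id = m[, 1L], subject_id = m[, 2L],
    percent_identity = num(3L, "percent identity"),
    align_length = num(4L, "alignment length", TRUE),
    query_start = num(7L, "query start", TRUE),
    query_end = num(8L, "query end", TRUE),
    subject_start = pmin(sstart, send) - 1L,
    subject_end = pmax(sstart, send),
    subject_strand = ifelse(sstart > send, "-", "+"),
    evalue = num(11L, "e-value"),
    bit_score = num(12L, "bit score"),
    query_frame = qframe
  )
}

empty_hits <- function() {
  tibble(query_id = character(), subject_id = character(),
         percent_identity = numeric(), align_length = integer(),
         query_start = integer(), query_end = integer(),
         subject_start = integer(), subject_end = integer(),
         subject_strand = character(), evalue = numeric(),
         bit_score = numeric(), query_frame = integer())
}

#' Write a hit table back to BLAST tabular format
#'
#' Reconstructs printed 1-based subject coordinates (inverted for `-` strand
#' subjects) from the normalised representation. Frame columns are written
#' when any `query_frame` is present. A commented header line records the
#' column order.
#'
#' @param hits Tibble as returned by [read_hit_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  minus <- hits$subject_strand == "-"
  sstart <- ifelse(minus, hits$subject_end, hits$subject_start + 1L)
  send <- ifelse(minus, hits$subject_start + 1L, hits$subject_end)
  frames <- !all(is.na(hits$query_frame))
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore",
            if (frames) c("qframe", "sframe"))
  body <- paste(hits$query_id, hits$subject_id,
                formatC(hits$percent_identity, format = "fg"),
                hits$align_length, 0L, 0L,
                hits$query_start, hits$query_end, sstart, send,
                formatC(hits$evalue, format = "g"),
                formatC(hits$bit_score, format = "fg"), sep = "\t")
  if (frames) {
    body <- paste(body, hits$query_frame, ifelse(minus, -1L, 1L), sep = "\t")
  }
  readr::write_lines(c(paste0("# ", paste(cols, collapse = "\t")),
                       if (nrow(hits)) body), path)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' BED coordinates are 0-based half-open and are taken as-is.
#'
#' @param path Path to a BED3+ file.
#' @return Tibble `contig`, `start`, `end`, and, when present, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  parsed <- parse_tabular_lines(path)
  if (!length(parsed$lines)) {
    return(tibble(contig = character(), start = integer(), end = integer()))
  }
  fields <- stringr::str_split(parsed$lines, "\t")
  nf <- min(lengths(fields))
  m <- t(vapply(fields, function(f) f[seq_len(nf)], character(nf)))
  out <- tibble(contig = m[, 1L],
                start = as.integer(m[, 2L]),
                end = as.integer(m[, 3L]))
  if (nf >= 4L) out$name <- m[, 4L]
  if (nf >= 5L) out$score <- suppressWarnings(as.numeric(m[, 5L]))
  if (nf >= 6L) out$strand <- m[, 6L]
  out
}

#' Read a gene-by-sample expression matrix
#'
#' Tab-separated, first column gene identifiers, remaining columns numeric
#' sample values (header row required). Values are assumed normalised.
#'
#' @param path Path to the TSV file.
#' @return Tibble with `gene_id` plus one numeric column per sample.
#' @export
read_expression <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(x)[1L] <- "gene_id"
  if (anyDuplicated(x$gene_id)) {
    abort("duplicate gene identifiers in expression matrix",
          class = "antisenser_parse_error")
  }
  if (anyDuplicated(names(x))) {
    abort("duplicate sample identifiers in expression matrix",
          class = "antisenser_parse_error")
  }
  x
}
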