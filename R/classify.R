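# Antisense overlap detection and classification.
#
# Five configuration classes for a pair of overlapping opposite-strand
# transcripts:
#   intronic - one transcript's genomic span lies entirely inside a single
#              intron of the other (the "host"); the classic embedded AST.
#   nested   - at least one exon of one transcript lies entirely inside an
#              intron of the other, without full embedding.
#   exonic   - the coding parts (CDS when both transcripts carry one,
#              otherwise exons) overlap, or the overlap matches no terminal
#              pattern.
#   utr3     - tail-to-tail: exon overlap confined to the 3'-terminal exons
#              of both transcripts, coding parts disjoint (convergent pair).
#   utr5     - head-to-head: same with the 5'-terminal exons (divergent pair).
#
# intronic and nested are evaluated per ordering (either transcript may be
# the host), so one unordered pair can yield two records; the symmetric
# classes are evaluated once per unordered pair, and only when no ordering
# produced an intronic or nested call.

AS_CLASSES <- c("intronic", "nested", "exonic", "utr3", "utr5")

#' Find opposite-strand overlapping transcript pairs
#'
#' Every unordered pair of transcripts on the same contig but opposite
#' strands whose genomic spans overlap by at least 1 bp (half-open
#' coordinates: abutting spans do not overlap).
#'
#' @param a An [annotation_set()].
#' @return Tibble with one row per unordered pair: `transcript_plus`,
#'   `transcript_minus`, `contig`.
#' @export
find_opposite_overlaps <- function(a) {
  sp <- transcript_spans(a)
  p <- filter(sp, .data$strand == "+")
  m <- filter(sp, .data$strand == "-")
  if (!nrow(p) || !nrow(m)) {
    return(tibble(transcript_plus = character(), transcript_minus = character(),
                  contig = character()))
  }
  hits <- purrr::map_dfr(intersect(unique(p$contig), unique(m$contig)),
    function(ctg) {
      pc <- filter(p, .data$contig == ctg)
      mc <- filter(m, .data$contig == ctg)
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(pc$start + 1L, pc$end),
        IRanges::IRanges(mc$start + 1L, mc$end),
        minoverlap = 1L
      )
      tibble(transcript_plus = pc$transcript_id[S4Vectors_from(ov)],
             transcript_minus = mc$transcript_id[S4Vectors_to(ov)],
             contig = ctg)
    })
  arrange(hits, .data$contig, .data$transcript_plus, .data$transcript_minus)
}

# thin wrappers so the Hits accessors are the only S4 touch points
S4Vectors_from <- function(x) S4Vectors::queryHits(x)
S4Vectors_to <- function(x) S4Vectors::subjectHits(x)

# transcript geometry bundle used by the per-pair classifier
tx_geometry <- function(a) {
  ex <- split(a$exons[c("start", "end")], a$exons$transcript_id)
  cd <- split(a$cds[c("start", "end")], a$cds$transcript_id)
  sp <- a$transcripts
  list(spans = sp, exons = ex, cds = cd)
}

intervals_overlap_any <- function(x, y) {
  if (!nrow(x) || !nrow(y)) return(FALSE)
  any(outer(x$start, y$end, `<`) & outer(x$end, y$start, `>`))
}

# for each row of x: does it overlap any interval of y?
overlaps_which <- function(x, y) {
  if (!nrow(x) || !nrow(y)) return(logical(nrow(x)))
  rowSums(outer(x$start, y$end, `<`) & outer(x$end, y$start, `>`)) > 0L
}

introns_of <- function(exons) {
  k <- nrow(exons)
  if (k < 2L) return(tibble(start = integer(), end = integer()))
  tibble(start = exons$end[-k], end = exons$start[-1L])
}

# intronic/nested evaluation of one ordering: host h over candidate AST s
ordered_class <- function(h_ex, s_ex) {
  intr <- introns_of(h_ex)
  if (!nrow(intr)) return(NULL)
  s_start <- min(s_ex$start); s_end <- max(s_ex$end)
  idx <- which(intr$start <= s_start & s_end <= intr$end)
  if (length(idx)) {
    return(list(cls = "intronic", intron_index = idx[1L],
                intron_length = intr$end[idx[1L]] - intr$start[idx[1L]]))
  }
  inside <- outer(s_ex$start, intr$start, `>=`) & outer(s_ex$end, intr$end, `<=`)
  if (any(inside)) return(list(cls = "nested", intron_index = NA_integer_,
                               intron_length = NA_integer_))
  NULL
}

# symmetric evaluation: exonic / utr3 / utr5 for a (+, -) transcript pair
symmetric_class <- function(p_ex, m_ex, p_cds, m_cds) {
  both_cds <- nrow(p_cds) > 0L && nrow(m_cds) > 0L
  if (both_cds && intervals_overlap_any(p_cds, m_cds)) return("exonic")
  p_hit <- which(overlaps_which(p_ex, m_ex))
  m_hit <- which(overlaps_which(m_ex, p_ex))
  if (!length(p_hit) || !length(m_hit)) return("exonic")
  # 3'-terminal exon: last in genome order for +, first for -
  p3 <- nrow(p_ex); p5 <- 1L
  m3 <- 1L; m5 <- nrow(m_ex)
  p_start <- min(p_ex$start); p_end <- max(p_ex$end)
  m_start <- min(m_ex$start); m_end <- max(m_ex$end)
  convergent <- p_start < m_start && p_end < m_end   # tail-to-tail ->  <-
  divergent <- m_start < p_start && m_end < p_end    # head-to-head <-  ->
  if (identical(p_hit, p3) && identical(m_hit, m3) && convergent) return("utr3")
  if (identical(p_hit, p5) && identical(m_hit, m5) && divergent) return("utr5")
  "exonic"
}

#' Classify one opposite-strand overlapping transcript pair
#'
#' Applies the precedence ladder intronic > nested > (exonic | utr3 | utr5).
#' Both orderings are evaluated for the asymmetric classes, so a single
#' unordered pair may yield two records (e.g. each transcript nested in the
#' other); the symmetric classes are assigned at most once per pair, with
#' the `+`-strand transcript reported in the `host_transcript` column purely
#' as a convention (symmetric overlaps have no biological host).
#'
#' @param a An [annotation_set()] containing both transcripts.
#' @param t1,t2 Transcript identifiers; must be on the same contig, opposite
#'   strands, with overlapping spans.
#' @return Tibble with 1-2 rows: `host_transcript`, `ast_transcript`, `class`,
#'   `host_intron_index` (1-based, intronic only), `host_intron_length`.
#' @export
classify_pair <- function(a, t1, t2) {
  geo <- tx_geometry(a)
  i1 <- match(t1, geo$spans$transcript_id)
  i2 <- match(t2, geo$spans$transcript_id)
  if (anyNA(c(i1, i2))) abort("unknown transcript id")
  classify_pair_impl(geo, i1, i2)
}

classify_pair_impl <- function(geo, i1, i2) {
  sp <- geo$spans
  if (sp$strand[i1] == sp$strand[i2] || sp$contig[i1] != sp$contig[i2]) {
    abort("transcripts must overlap on opposite strands of one contig")
  }
  ids <- sp$transcript_id
  e1 <- geo$exons[[ids[i1]]]; e2 <- geo$exons[[ids[i2]]]
  rec <- list()
  r12 <- ordered_class(e1, e2)   # i1 host, i2 AST
  r21 <- ordered_class(e2, e1)
  if (!is.null(r12) && !is.null(r21) &&
      r12$cls == "intronic" && r21$cls == "intronic") {
    abort("mutually intronic pair: geometrically impossible for valid models")
  }
  add <- function(h, s, r) {
    tibble(host_transcript = ids[h], ast_transcript = ids[s], class = r$cls,
           host_intron_index = r$intron_index,
           host_intron_length = r$intron_length)
  }
  if (!is.null(r12)) rec <- c(rec, list(add(i1, i2, r12)))
  if (!is.null(r21)) rec <- c(rec, list(add(i2, i1, r21)))
  if (length(rec)) return(bind_rows(rec))

  # symmetric classes, evaluated once with the + transcript as p
  if (sp$strand[i1] == "+") { p <- i1; m <- i2 } else { p <- i2; m <- i1 }
  cls <- symmetric_class(geo$exons[[ids[p]]], geo$exons[[ids[m]]],
                         geo$cds[[ids[p]]] %||% tibble(start = integer(), end = integer()),
                         geo$cds[[ids[m]]] %||% tibble(start = integer(), end = integer()))
  tibble(host_transcript = ids[p], ast_transcript = ids[m], class = cls,
         host_intron_index = NA_integer_, host_intron_length = NA_integer_)
}

#' Classify all antisense overlaps in an annotation
#'
#' Detects every opposite-strand overlapping transcript pair and classifies
#' each (see [classify_pair()]).
#'
#' @param a An [annotation_set()].
#' @return Tibble with one row per classified record: `host_transcript`,
#'   `ast_transcript`, `host_gene`, `ast_gene`, `class`, `host_intron_index`,
#'   `host_intron_length`, `contig`.
#' @examples
#' cfg <- simulation_config(seed = 7, n_background_genes = 20,
#'                          class_counts = c(intronic = 3, nested = 1,
#'                                           exonic = 1, utr3 = 1, utr5 = 0))
#' sim <- simulate_annotation(cfg)
#' classify_antisense(sim$annotation)
#' @export
classify_antisense <- function(a) {
  pairs <- find_opposite_overlaps(a)
  geo <- tx_geometry(a)
  out <- purrr::map2_dfr(
    match(pairs$transcript_plus, geo$spans$transcript_id),
    match(pairs$transcript_minus, geo$spans$transcript_id),
    function(i, j) classify_pair_impl(geo, i, j)
  )
  if (!nrow(out)) {
    return(tibble(host_transcript = character(), ast_transcript = character(),
                  host_gene = character(), ast_gene = character(),
                  class = character(), host_intron_index = integer(),
                  host_intron_length = integer(), contig = character()))
  }
  gene_of <- setNames(geo$spans$gene_id, geo$spans$transcript_id)
  contig_of <- setNames(geo$spans$contig, geo$spans$transcript_id)
  out %>%
    mutate(host_gene = unname(gene_of[.data$host_transcript]),
           ast_gene = unname(gene_of[.data$ast_transcript]),
           contig = unname(contig_of[.data$host_transcript])) %>%
    select("host_transcript", "ast_transcript", "host_gene", "ast_gene",
           "class", "host_intron_index", "host_intron_length", "contig")
}

#' Summarise a classified set of antisense overlaps
#'
#' Per-class record counts plus, for the intronic class (the antisense gene
#' pairs proper), the number of distinct AST transcripts, distinct host
#' genes, and distinct (host gene, AST gene) combinations -- the three
#' levels at which embedded antisense transcription is usually reported.
#'
#' @param pairs Output of [classify_antisense()].
#' @return One-row tibble: `n_records`, `n_intronic`, `n_nested`, `n_exonic`,
#'   `n_utr3`, `n_utr5`, `n_unique_asts`, `n_unique_hosts`,
#'   `n_gene_level_pairs`.
#' @export
summarize_antisense <- function(pairs) {
  cls_n <- function(cl) sum(pairs$class == cl)
  intr <- filter(pairs, .data$class == "intronic")
  tibble(
    n_records = nrow(pairs),
    n_intronic = cls_n("intronic"), n_nested = cls_n("nested"),
    n_exonic = cls_n("exonic"), n_utr3 = cls_n("utr3"), n_utr5 = cls_n("utr5"),
    n_unique_asts = n_distinct(intr$ast_transcript),
    n_unique_hosts = n_distinct(intr$host_gene),
    n_gene_level_pairs = nrow(distinct(intr, .data$host_gene, .data$ast_gene))
  )
}
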