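# Independent oracles and fixture builders. All oracles work on explicit
# per-base integer sets or full enumeration, never on the package's
# interval arithmetic.

# ---- fixture builders -------------------------------------------------

# quick annotation from a list of transcripts:
#   list(id, gene, contig, strand, exons = matrix/list of c(start, end), cds)
make_annotation <- function(...) {
  txs <- list(...)
  tx <- dplyr::bind_rows(lapply(txs, function(t) {
    tibble::tibble(transcript_id = t$id,
                   gene_id = t$gene %||% t$id,
                   contig = t$contig %||% "chr1",
                   strand = t$strand)
  }))
  part <- function(field) {
    dplyr::bind_rows(lapply(txs, function(t) {
      p <- t[[field]]
      if (is.null(p)) return(NULL)
      m <- do.call(rbind, p)
      tibble::tibble(transcript_id = t$id, start = m[, 1], end = m[, 2])
    }))
  }
  ex <- part("exons")
  cd <- part("cds")
  annotation_set(tx, ex, if (!is.null(cd) && nrow(cd)) cd else NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random dense annotation on one short contig; overlaps of every flavour
random_annotation <- function(n_genes = 12, contig_len = 3000) {
  txs <- lapply(seq_len(n_genes), function(i) {
    n_ex <- sample(1:4, 1)
    ex_len <- sample(5:60, n_ex, replace = TRUE)
    in_len <- if (n_ex > 1) sample(5:80, n_ex - 1, replace = TRUE) else integer()
    width <- sum(ex_len) + sum(in_len)
    s <- sample.int(max(1, contig_len - width), 1)
    starts <- s + cumsum(c(0, head(ex_len, -1) + in_len))
    list(id = sprintf("rt%02d", i), gene = sprintf("rg%02d", i),
         strand = sample(c("+", "-"), 1),
         exons = lapply(seq_len(n_ex), function(k) c(starts[k], starts[k] + ex_len[k])))
  })
  do.call(make_annotation, txs)
}

# ---- per-base classifier oracle ---------------------------------------

bases_of <- function(tbl) {
  if (!nrow(tbl)) return(integer())
  unlist(Map(function(s, e) seq.int(s, e - 1L), tbl$start, tbl$end))
}

# classify one unordered opposite-strand overlapping pair by explicit base
# sets; returns tibble(host, ast, class) records (host = "+" member for
# symmetric classes)
oracle_classify_pair <- function(a, t1, t2) {
  ex <- function(t) a$exons[a$exons$transcript_id == t, c("start", "end")]
  cd <- function(t) a$cds[a$cds$transcript_id == t, c("start", "end")]
  info <- a$transcripts[match(c(t1, t2), a$transcripts$transcript_id), ]
  intr <- function(t) {
    e <- ex(t)
    k <- nrow(e)
    if (k < 2) return(list())
    lapply(seq_len(k - 1), function(i) seq.int(e$end[i], e$start[i + 1] - 1L))
  }
  span_bases <- function(t) {
    e <- ex(t)
    seq.int(min(e$start), max(e$end) - 1L)
  }
  ordered <- function(h, s) {
    ib <- intr(h)
    if (!length(ib)) return(NULL)
    sb <- span_bases(s)
    for (i in seq_along(ib)) {
      if (all(sb %in% ib[[i]])) {
        return(tibble::tibble(host = h, ast = s, class = "intronic"))
      }
    }
    se <- ex(s)
    for (j in seq_len(nrow(se))) {
      eb <- seq.int(se$start[j], se$end[j] - 1L)
      if (any(vapply(ib, function(x) all(eb %in% x), TRUE))) {
        return(tibble::tibble(host = h, ast = s, class = "nested"))
      }
    }
    NULL
  }
  recs <- dplyr::bind_rows(ordered(t1, t2), ordered(t2, t1))
  if (nrow(recs)) return(recs)

  p <- if (info$strand[1] == "+") t1 else t2
  m <- if (info$strand[1] == "+") t2 else t1
  pe <- ex(p); me <- ex(m)
  peb <- bases_of(pe); meb <- bases_of(me)
  ov <- intersect(peb, meb)
  pc <- bases_of(cd(p)); mc <- bases_of(cd(m))
  cls <- if (length(pc) && length(mc) && length(intersect(pc, mc))) {
    "exonic"
  } else if (!length(ov)) {
    "exonic"   # spans overlap but exon bases do not (cannot happen here)
  } else {
    p_hit <- which(vapply(seq_len(nrow(pe)), function(k) {
      any(seq.int(pe$start[k], pe$end[k] - 1L) %in% ov)
    }, TRUE))
    m_hit <- which(vapply(seq_len(nrow(me)), function(k) {
      any(seq.int(me$start[k], me$end[k] - 1L) %in% ov)
    }, TRUE))
    p_sb <- range(peb); m_sb <- range(meb)
    contained <- (p_sb[1] >= m_sb[1] && p_sb[2] <= m_sb[2]) ||
      (m_sb[1] >= p_sb[1] && m_sb[2] <= p_sb[2])
    conv <- !contained && p_sb[1] < m_sb[1]   # + left of -, tail-to-tail
    div <- !contained && m_sb[1] < p_sb[1]
    if (identical(p_hit, nrow(pe)) && identical(m_hit, 1L) && conv) {
      "utr3"
    } else if (identical(p_hit, 1L) && identical(m_hit, nrow(me)) && div) {
      "utr5"
    } else "exonic"
  }
  tibble::tibble(host = p, ast = m, class = cls)
}

# all opposite-strand overlapping pairs by brute-force span scan
oracle_overlaps <- function(a) {
  sp <- transcript_spans(a)
  out <- list()
  n <- nrow(sp)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && sp$contig[i] == sp$contig[j] &&
        sp$strand[i] != sp$strand[j] &&
        sp$start[i] < sp$end[j] && sp$end[i] > sp$start[j]) {
      out[[length(out) + 1L]] <- c(sp$transcript_id[i], sp$transcript_id[j])
    }
  }
  out
}

oracle_classify_all <- function(a) {
  dplyr::bind_rows(
    list(tibble::tibble(host = character(), ast = character(),
                        class = character())),
    lapply(oracle_overlaps(a), function(p) {
      oracle_classify_pair(a, p[1], p[2])
    }))
}

# ---- geometry transforms ---------------------------------------------

shift_annotation <- function(a, by) {
  annotation_set(
    dplyr::select(a$transcripts, transcript_id, gene_id, contig, strand),
    dplyr::mutate(a$exons[c("transcript_id", "start", "end")],
                  start = start + by, end = end + by),
    if (nrow(a$cds)) dplyr::mutate(a$cds, start = start + by, end = end + by)
  )
}

flip_strands <- function(a) {
  annotation_set(
    dplyr::mutate(
      dplyr::select(a$transcripts, transcript_id, gene_id, contig, strand),
      strand = ifelse(strand == "+", "-", "+")),
    a$exons[c("transcript_id", "start", "end")],
    if (nrow(a$cds)) a$cds
  )
}

# reverse complement: reflect coordinates around C and swap strands
revcomp_annotation <- function(a, C = 10000L) {
  refl <- function(tbl) {
    dplyr::mutate(tbl[c("transcript_id", "start", "end")],
                  new_start = C - end, end = C - start,
                  start = new_start)[c("transcript_id", "start", "end")]
  }
  annotation_set(
    dplyr::mutate(
      dplyr::select(a$transcripts, transcript_id, gene_id, contig, strand),
      strand = ifelse(strand == "+", "-", "+")),
    refl(a$exons),
    if (nrow(a$cds)) refl(a$cds)
  )
}

# ---- statistics oracles ----------------------------------------------

oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# exact one/two-sided rank-sum p by enumeration of all C(n, n1) arrangements
oracle_ranksum_p <- function(a, b, alternative) {
  n1 <- length(a); n <- n1 + length(b)
  pooled <- c(a, b)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  combs <- utils::combn(n, n1)
  us <- apply(combs, 2, function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  switch(alternative,
         a_greater = mean(us >= u_obs),
         a_less = mean(us <= u_obs),
         two_sided = min(1, 2 * min(mean(us >= u_obs), mean(us <= u_obs))))
}

# brute-force complement of masks by per-base marking
oracle_cne <- function(contig_len, masks, min_len) {
  covered <- rep(FALSE, contig_len)
  for (i in seq_len(nrow(masks))) {
    if (masks$end[i] > masks$start[i]) {
      covered[(masks$start[i] + 1):masks$end[i]] <- TRUE
    }
  }
  r <- rle(!covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths >= min_len
  tibble::tibble(start = starts[keep], end = ends[keep])
}

# brute-force conservation call over all (contig, strand, ast hit) triples
oracle_call_pair <- function(host_hits, ast_hits, evalue_max = 0.001) {
  h <- host_hits[host_hits$evalue < evalue_max, ]
  s <- ast_hits[ast_hits$evalue < evalue_max, ]
  if (!nrow(h) || !nrow(s)) return(FALSE)
  for (ctg in unique(h$subject_id)) for (str in c("+", "-")) {
    hh <- h[h$subject_id == ctg & h$subject_strand == str, ]
    if (!nrow(hh)) next
    lo <- min(hh$subject_start); hi <- max(hh$subject_end)
    opp <- if (str == "+") "-" else "+"
    for (k in seq_len(nrow(s))) {
      if (s$subject_id[k] == ctg && s$subject_strand[k] == opp &&
          s$subject_start[k] >= lo && s$subject_end[k] <= hi) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# random hit-table pair for conservation oracle tests
random_hit_tables <- function() {
  mk <- function(n, role) {
    if (!n) return(antisenser:::empty_hits())
    tibble::tibble(
      query_id = role, subject_id = sample(c("ctgA", "ctgB"), n, TRUE),
      percent_identity = 50, align_length = 100L,
      query_start = 1L, query_end = 100L,
      subject_start = sample(0:900, n, TRUE),
      subject_end = 0L, subject_strand = sample(c("+", "-"), n, TRUE),
      evalue = 10^-sample(c(1, 2, 4, 8), n, TRUE),  # some fail the 1e-3 cut
      bit_score = 100, query_frame = NA_integer_
    ) |> dplyr::mutate(subject_end = subject_start + sample(20:120, n, TRUE))
  }
  list(host = mk(sample(0:5, 1), "host"), ast = mk(sample(0:5, 1), "ast"))
}
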