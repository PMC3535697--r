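# Fixture builders and independent brute-force oracles used across the
# suite.  The oracles deliberately share no code with the package
# internals: they enumerate pairs/trios/bases directly.

# Build an exon-level transcript tibble from a named list of exon
# matrices: tx_tbl(list(A = rbind(c(0,100), c(200,300))), strand = "+")
tx_tbl <- function(exons, chrom = "chr1", strand = "+", gene_id = "G") {
  rows <- lapply(names(exons), function(tid) {
    m <- exons[[tid]]
    tibble::tibble(transcript_id = tid, gene_id = gene_id, chrom = chrom,
                   strand = strand,
                   start = as.integer(m[, 1]), end = as.integer(m[, 2]))
  })
  dplyr::bind_rows(rows)
}

# The worked two-isoform gene: three shared-boundary exons, one skipped.
two_isoform_gene <- function() {
  tx_tbl(list(A = rbind(c(0, 100), c(200, 300), c(400, 500)),
              B = rbind(c(0, 100), c(400, 500))))
}

# The published minus-strand worked example (1-based inclusive loci
# converted to 0-based half-open): cassette chr1:93073138-93073284,
# constitutive exons chr1:93089733-93089891 (5') and
# chr1:93070864-93070959 (3').
fig_example_gene <- function() {
  tx_tbl(list(inc = rbind(c(93070863, 93070959),
                          c(93073137, 93073284),
                          c(93089732, 93089891)),
              exc = rbind(c(93070863, 93070959),
                          c(93089732, 93089891))),
         chrom = "chr1", strand = "-", gene_id = "")
}

# Random gene group built on a shared exon skeleton so that isoform
# chains coincide often enough to create cassette evidence; a fraction
# of boundaries are jittered to create near-miss decoys.
random_gene <- function(max_isoforms = 6, max_exons = 8, chrom = "chr1",
                        gene_id = "G") {
  n_skel <- sample(3:max_exons, 1)
  lens <- sample(10:60, n_skel, replace = TRUE)
  gaps <- sample(20:80, n_skel, replace = TRUE)
  starts <- cumsum(gaps + c(0, lens[-n_skel]))
  ends <- starts + lens
  strand <- sample(c("+", "-"), 1)
  n_iso <- sample(1:max_isoforms, 1)
  exons <- list()
  for (k in seq_len(n_iso)) {
    keep <- sort(sample(n_skel, sample(1:n_skel, 1)))
    s <- starts[keep]
    e <- ends[keep]
    if (length(keep) > 0 && runif(1) < 0.3) {
      j <- sample(length(keep), 1)
      if (runif(1) < 0.5) s[j] <- s[j] + sample(1:5, 1) else e[j] <- e[j] - sample(1:5, 1)
      if (s[j] >= e[j]) s[j] <- e[j] - 1L
    }
    exons[[sprintf("T%d", k)]] <- cbind(s, e)
  }
  tx_tbl(exons, chrom = chrom, strand = strand, gene_id = gene_id)
}

# Independent oracle for detect_cassette_events(): double loop over all
# isoform pairs and exon trios.  Returns a sorted character key per
# event: chrom|strand|trio coords (genome order)|including|skipping.
bf_detect_keys <- function(gene_exons) {
  chains <- lapply(split(gene_exons, gene_exons$transcript_id), function(d) {
    d[order(d$start), c("start", "end")]
  })
  keys <- character()
  for (a in names(chains)) {
    ca <- chains[[a]]
    na <- nrow(ca)
    if (na < 3) next
    for (i in 2:(na - 1)) {
      trio <- c(ca$start[i - 1], ca$end[i - 1], ca$start[i], ca$end[i],
                ca$start[i + 1], ca$end[i + 1])
      including <- character()
      skipping <- character()
      for (b in names(chains)) {
        cb <- chains[[b]]
        nb <- nrow(cb)
        if (nb >= 3) {
          for (j in 2:(nb - 1)) {
            if (all(c(cb$start[j - 1], cb$end[j - 1], cb$start[j], cb$end[j],
                      cb$start[j + 1], cb$end[j + 1]) == trio)) {
              including <- c(including, b)
            }
          }
        }
        if (nb >= 2) {
          for (j in 1:(nb - 1)) {
            if (all(c(cb$start[j], cb$end[j], cb$start[j + 1], cb$end[j + 1]) ==
                    trio[c(1, 2, 5, 6)])) {
              skipping <- c(skipping, b)
            }
          }
        }
      }
      if (length(including) > 0 && length(skipping) > 0) {
        keys <- c(keys, paste(
          gene_exons$chrom[1], gene_exons$strand[1],
          paste(trio, collapse = ","),
          paste(sort(unique(including)), collapse = ","),
          paste(sort(unique(skipping)), collapse = ","), sep = "|"))
      }
    }
  }
  sort(unique(keys))
}

# Render a detected event table in the same key space (genome order).
event_keys <- function(events) {
  if (nrow(events) == 0) return(character())
  keys <- vapply(seq_len(nrow(events)), function(i) {
    e <- events[i, ]
    left_first <- e$flank5_start < e$flank3_start
    f_left <- if (left_first) c(e$flank5_start, e$flank5_end) else c(e$flank3_start, e$flank3_end)
    f_right <- if (left_first) c(e$flank3_start, e$flank3_end) else c(e$flank5_start, e$flank5_end)
    paste(e$chrom, e$strand,
          paste(c(f_left, e$cassette_start, e$cassette_end, f_right),
                collapse = ","),
          paste(sort(strsplit(e$including, ",")[[1]]), collapse = ","),
          paste(sort(strsplit(e$skipping, ",")[[1]]), collapse = ","), sep = "|")
  }, character(1))
  sort(unique(keys))
}

# Connected components of the pairwise exon-overlap graph (BFS),
# independent of the package's sweep/union-find.
bf_components <- function(transcripts) {
  tids <- sort(unique(transcripts$transcript_id))
  n <- length(tids)
  adj <- matrix(FALSE, n, n)
  info <- split(transcripts, transcripts$transcript_id)[tids]
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      a <- info[[i]]
      b <- info[[j]]
      if (a$chrom[1] != b$chrom[1] || a$strand[1] != b$strand[1]) next
      hit <- any(outer(a$start, b$end, `<`) & outer(a$end, b$start, `>`))
      if (hit) adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  # also split components by chrom+strand label for transcripts that
  # never overlap anything
  stats::setNames(comp, tids)
}

expect_events_equal <- function(a, b) {
  cols <- c("event_id", "chrom", "strand", "flank5_start", "flank5_end",
            "cassette_start", "cassette_end", "flank3_start", "flank3_end",
            "including", "skipping")
  a <- dplyr::arrange(tibble::as_tibble(a)[cols], event_id)
  b <- dplyr::arrange(tibble::as_tibble(b)[cols], event_id)
  expect_equal(a, b, ignore_attr = TRUE)
}

# Exon-structure comparison that ignores gene ids (BED12 drops them).
exon_structure <- function(transcripts) {
  dplyr::arrange(
    tibble::as_tibble(transcripts)[c("transcript_id", "chrom", "strand",
                                     "start", "end")],
    transcript_id, start)
}
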