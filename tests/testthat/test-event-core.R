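test_that("the two-isoform skipped-exon gene yields count string [2-0-1-0-2] and one event", {
  gene <- two_isoform_gene()
  seg <- flatten_units(gene)
  expect_equal(seg$count, c(2L, 0L, 1L, 0L, 2L))
  expect_equal(count_string(seg), "[2-0-1-0-2]")
  expect_equal(seg$covering[[3]], "A")
  expect_equal(seg$covering[[1]], c("A", "B"))

  ev <- detect_cassette_events(gene)
  expect_equal(nrow(ev), 1L)
  expect_equal(c(ev$cassette_start, ev$cassette_end), c(200L, 300L))
  expect_equal(c(ev$flank5_start, ev$flank5_end), c(0L, 100L))
  expect_equal(c(ev$flank3_start, ev$flank3_end), c(400L, 500L))
  expect_equal(ev$including, "A")
  expect_equal(ev$skipping, "B")
})

test_that("a single-isoform gene projects to [1-0-1-0-1] and no events", {
  gene <- tx_tbl(list(A = rbind(c(0, 100), c(200, 300), c(400, 500))))
  seg <- flatten_units(gene)
  expect_equal(seg$count, c(1L, 0L, 1L, 0L, 1L))
  expect_true(all(vapply(seg$covering[seg$kind == "unit"],
                         identical, logical(1), "A")))
  expect_equal(nrow(detect_cassette_events(gene)), 0L)
})

test_that("segment covering sets match a per-base membership oracle", {
  set.seed(2024)
  for (rep in 1:30) {
    gene <- random_gene()
    seg <- flatten_units(gene)
    # tiling: consecutive, non-overlapping, spanning the exon union
    expect_equal(seg$start[-1], seg$end[-nrow(seg)])
    expect_equal(seg$start[1], min(gene$start))
    expect_equal(seg$end[nrow(seg)], max(gene$end))
    expect_gt(seg$count[1], 0)
    expect_gt(seg$count[nrow(seg)], 0)
    # adjacent segments differ in covering set (maximality)
    if (nrow(seg) > 1) {
      same <- mapply(identical, seg$covering[-1], seg$covering[-nrow(seg)])
      expect_false(any(same))
    }
    for (b in seq(min(gene$start), max(gene$end) - 1)) {
      at_base <- sort(unique(gene$transcript_id[gene$start <= b & gene$end > b]))
      s <- which(seg$start <= b & seg$end > b)
      expect_equal(seg$covering[[s]], at_base)
    }
  }
})

test_that("conservation: sum of count x length equals total isoform exon length", {
  set.seed(515)
  for (rep in 1:50) {
    gene <- random_gene()
    seg <- flatten_units(gene)
    expect_equal(sum(seg$count * (seg$end - seg$start)),
                 sum(gene$end - gene$start))
  }
})

test_that("detection matches the brute-force pairwise trio scan on random groups", {
  set.seed(99)
  for (rep in 1:100) {
    gene <- random_gene()
    expect_equal(event_keys(detect_cassette_events(gene)),
                 bf_detect_keys(gene))
  }
})

test_that("the worked minus-strand example yields one event with strand-correct flanks", {
  ev <- find_events(fig_example_gene())
  expect_equal(nrow(ev), 1L)
  # 1-based inclusive loci as published
  expect_equal(c(ev$cassette_start + 1L, ev$cassette_end),
               c(93073138L, 93073284L))
  expect_equal(c(ev$flank5_start + 1L, ev$flank5_end),
               c(93089733L, 93089891L))
  expect_equal(c(ev$flank3_start + 1L, ev$flank3_end),
               c(93070864L, 93070959L))
  expect_equal(ev$strand, "-")
  expect_equal(ev$including, "inc")
  expect_equal(ev$skipping, "exc")
})

test_that("grouping honours gene ids, clusters anonymous transcripts, separates strands", {
  named <- tx_tbl(list(T1 = rbind(c(0, 100)), T2 = rbind(c(50, 150))),
                  gene_id = "G1")
  g <- group_transcripts(named)
  expect_equal(unique(g$gene_id), "G1")

  anon <- dplyr::bind_rows(
    tx_tbl(list(A = rbind(c(0, 100), c(200, 300))), gene_id = "", strand = "+"),
    tx_tbl(list(B = rbind(c(250, 350))), gene_id = "", strand = "+"),
    tx_tbl(list(C = rbind(c(0, 100), c(200, 300))), gene_id = "", strand = "-"))
  g <- group_transcripts(anon)
  gid <- function(t) unique(g$gene_id[g$transcript_id == t])
  expect_equal(gid("A"), gid("B"))     # exonic overlap links them
  expect_false(gid("A") == gid("C"))   # same loci, opposite strand
  expect_match(gid("C"), "^GRP_chr1_-_1$")
})

test_that("anonymous grouping equals connected components of the overlap graph", {
  set.seed(314)
  for (rep in 1:5) {
    txs <- lapply(1:40, function(i) {
      n <- sample(1:4, 1)
      s <- sort(sample(0:2000, n))
      tx_tbl(stats::setNames(list(cbind(s * 5L, s * 5L + sample(10:200, n, TRUE))),
                             sprintf("R%03d", i)),
             chrom = sample(c("c1", "c2"), 1),
             strand = sample(c("+", "-"), 1), gene_id = "")
    })
    pool <- dplyr::bind_rows(txs)
    # drop invalid overlaps within a transcript
    pool <- dplyr::bind_rows(lapply(split(pool, pool$transcript_id), function(d) {
      d <- d[order(d$start), ]
      keep <- c(TRUE, d$start[-1] > cummax(d$end[-nrow(d)]))
      d[keep, ]
    }))
    g <- group_transcripts(pool)
    ours <- stats::setNames(g$gene_id[!duplicated(g$transcript_id)],
                            g$transcript_id[!duplicated(g$transcript_id)])
    ref <- bf_components(pool)
    ours <- ours[names(ref)]
    # identical partitions: same co-membership for every pair
    expect_equal(outer(ours, ours, `==`), outer(ref, ref, `==`),
                 ignore_attr = TRUE)
  }
})

test_that("find_events is invariant to input order and across formats", {
  sim <- generate_annotation(sim_config(n_genes = 20, seed = 5))
  ev <- find_events(sim$transcripts)
  shuffled <- sim$transcripts[sample(nrow(sim$transcripts)), ]
  expect_events_equal(find_events(shuffled), ev)

  gtf <- withr::local_tempfile(fileext = ".gtf")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_gtf(sim$transcripts, gtf)
  write_bed12(sim$transcripts, bed)
  ev_gtf <- find_events(read_gtf(gtf))
  ev_bed <- find_events(read_bed12(bed))
  # BED carries no gene ids, so including/skipping sets and coordinates
  # must still agree exactly
  expect_events_equal(ev_gtf, ev)
  expect_events_equal(ev_bed, ev)
  expect_equal(nrow(find_events(sim$transcripts[0, ])), 0L)
})

test_that("strand mirror symmetry maps events to reflected events", {
  set.seed(42)
  for (rep in 1:20) {
    gene <- random_gene()
    C <- max(gene$end) + 17L
    mirrored <- gene
    mirrored$start <- C - gene$end
    mirrored$end <- C - gene$start
    mirrored$strand <- ifelse(gene$strand == "+", "-", "+")
    ev <- detect_cassette_events(gene)
    mv <- detect_cassette_events(mirrored)
    expect_equal(nrow(mv), nrow(ev))
    if (nrow(ev) > 0) {
      # transcription-order flanks are preserved under reflection
      key <- function(e) paste(C - e$flank5_end, C - e$flank5_start,
                               C - e$cassette_end, C - e$cassette_start,
                               C - e$flank3_end, C - e$flank3_start,
                               e$including, e$skipping)
      mkey <- function(e) paste(e$flank5_start, e$flank5_end,
                                e$cassette_start, e$cassette_end,
                                e$flank3_start, e$flank3_end,
                                e$including, e$skipping)
      expect_equal(sort(key(ev)), sort(mkey(mv)))
    }
  }
})

test_that("adding an isoform never removes an existing event", {
  set.seed(77)
  for (rep in 1:20) {
    gene <- random_gene(max_isoforms = 5)
    extra <- random_gene(max_isoforms = 1)
    extra <- extra[extra$transcript_id == extra$transcript_id[1], ]
    extra$transcript_id <- "EXTRA"
    extra$strand <- gene$strand[1]
    before <- detect_cassette_events(gene)
    after <- detect_cassette_events(dplyr::bind_rows(gene, extra))
    trio_key <- function(e) paste(e$chrom, e$strand, e$flank5_start,
                                  e$flank5_end, e$cassette_start,
                                  e$cassette_end, e$flank3_start, e$flank3_end)
    expect_true(all(trio_key(before) %in% trio_key(after)))
  }
})

test_that("two-isoform events correspond exactly to [2-0-1-0-2] windows", {
  set.seed(123)
  n_checked <- 0
  for (rep in 1:60) {
    gene <- random_gene(max_isoforms = 2)
    if (dplyr::n_distinct(gene$transcript_id) != 2) next
    seg <- flatten_units(gene)
    ev <- detect_cassette_events(gene)
    # every event's trio window reads 2-0-1-0-2 in the segment profile
    if (nrow(ev) > 0) {
      for (i in seq_len(nrow(ev))) {
        left <- min(ev$flank5_start[i], ev$flank3_start[i])
        cs <- ev$cassette_start[i]
        ce <- ev$cassette_end[i]
        w <- which(seg$start >= left & seg$end <= max(ev$flank5_end[i],
                                                      ev$flank3_end[i]))
        counts <- seg$count[w]
        core <- which(seg$start[w] == cs)
        expect_equal(seg$count[w][c(core - 1L, core, core + 1L)], c(0L, 1L, 0L))
        expect_equal(counts[1], 2L)
        expect_equal(counts[length(counts)], 2L)
        n_checked <- n_checked + 1
      }
    }
  }
  expect_gt(n_checked, 0)
})
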