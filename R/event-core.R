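#' Group transcripts into genes
#'
#' Transcripts carrying a non-empty `gene_id` (GTF input) are grouped by
#' `(gene_id, chrom, strand)`.  Transcripts with an empty `gene_id`
#' (BED12 input) are clustered by single-linkage exonic overlap on the
#' same chromosome and strand; each cluster receives a synthesized id
#' `GRP_<chrom>_<strand>_<k>`, numbered by cluster span along the
#' chromosome.  Output order is deterministic and independent of input
#' order: groups sorted by span, exons sorted within transcripts.
#'
#' @param transcripts Exon-level transcript tibble.
#' @return The same tibble with every `gene_id` non-empty, in canonical
#'   group order.
#' @export
group_transcripts <- function(transcripts) {
  validate_transcripts(transcripts)
  if (nrow(transcripts) == 0) return(empty_transcripts())
  anon <- transcripts |> filter(.data$gene_id == "")
  named <- transcripts |> filter(.data$gene_id != "")
  if (nrow(anon) > 0) {
    clustered <- anon |>
      group_by(.data$chrom, .data$strand) |>
      dplyr::group_modify(~ cluster_by_overlap(.x)) |>
      ungroup()
    ## number clusters by span start within each chrom+strand
    clustered <- clustered |>
      group_by(.data$chrom, .data$strand, .data$.cluster) |>
      mutate(.cl_start = min(.data$start)) |>
      group_by(.data$chrom, .data$strand) |>
      mutate(gene_id = sprintf("GRP_%s_%s_%d", .data$chrom, .data$strand,
                               match(.data$.cluster,
                                     unique(.data$.cluster[order(.data$.cl_start,
                                                                 .data$.cluster)])))) |>
      ungroup() |>
      select(dplyr::all_of(transcript_cols))
    out <- bind_rows(named, clustered)
  } else {
    out <- named
  }
  arrange_groups(out)
}

## Single-linkage clustering of transcripts by exon overlap within one
## chrom+strand.  Overlap-connected runs of exon intervals (half-open:
## touching exons do not overlap) are found by a sweep; transcripts with
## exons in the same run are merged with union-find, so the result equals
## the connected components of the pairwise transcript-overlap graph.
cluster_by_overlap <- function(exons) {
  tids <- unique(exons$transcript_id)
  parent <- seq_along(tids)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  ord <- order(exons$start, exons$end)
  tx_idx <- match(exons$transcript_id, tids)[ord]
  starts <- exons$start[ord]
  ends <- exons$end[ord]
  run_max <- -Inf
  run_rep <- NA_integer_
  for (k in seq_along(starts)) {
    if (k > 1L && starts[k] < run_max) {
      a <- find(run_rep)
      b <- find(tx_idx[k])
      if (a != b) parent[a] <- b
      run_max <- max(run_max, ends[k])
    } else {
      run_max <- ends[k]
    }
    run_rep <- tx_idx[k]
  }
  comp <- vapply(seq_along(tids), find, integer(1))
  exons |> mutate(.cluster = comp[match(.data$transcript_id, tids)])
}

## Deterministic ordering: groups by (chrom, span start, span end,
## gene_id), then transcripts, then exon start.
arrange_groups <- function(transcripts) {
  spans <- transcripts |>
    group_by(.data$gene_id, .data$chrom, .data$strand) |>
    summarise(.g_start = min(.data$start), .g_end = max(.data$end),
              .groups = "drop")
  transcripts |>
    left_join(spans, by = c("gene_id", "chrom", "strand")) |>
    arrange(.data$chrom, .data$.g_start, .data$.g_end, .data$gene_id,
            .data$strand, .data$transcript_id, .data$start) |>
    select(dplyr::all_of(transcript_cols))
}

#' Partition a gene's exon union into minimum non-overlapping exon units
#'
#' The segment boundaries are exactly the sorted distinct exon start/end
#' coordinates of the group, restricted to the exon-union span.  Each
#' segment's covering set lists the isoforms with an exon fully
#' containing it; segments with no coverage are gaps (count 0).  The
#' ordered per-segment isoform counts form the gene's count string, the
#' pattern matched for event detection (for two isoforms,
#' `[2-0-1-0-2]` signals a cassette exon).
#'
#' @param gene_exons Exon-level tibble for a single gene (one `gene_id`,
#'   one chromosome and strand).
#' @return A tibble of class `ase_segments` with columns `gene_id`,
#'   `chrom`, `strand`, `start`, `end`, `count`, `kind` (`"unit"` or
#'   `"gap"`) and list-column `covering`; segments tile the gene span in
#'   genome order.
#' @export
flatten_units <- function(gene_exons) {
  validate_transcripts(gene_exons)
  if (nrow(gene_exons) == 0) {
    abort("flatten_units() needs at least one exon",
          class = "altevents_validation_error")
  }
  if (dplyr::n_distinct(gene_exons$gene_id) != 1 ||
      dplyr::n_distinct(gene_exons$chrom) != 1 ||
      dplyr::n_distinct(gene_exons$strand) != 1) {
    abort("flatten_units() expects a single gene group; run group_transcripts() first",
          class = "altevents_validation_error")
  }
  bounds <- sort(unique(c(gene_exons$start, gene_exons$end)))
  seg_start <- bounds[-length(bounds)]
  seg_end <- bounds[-1]
  covering <- purrr::map2(seg_start, seg_end, function(s, e) {
    sort(unique(gene_exons$transcript_id[gene_exons$start <= s &
                                           gene_exons$end >= e]))
  })
  segs <- tibble(
    gene_id = gene_exons$gene_id[1],
    chrom = gene_exons$chrom[1],
    strand = gene_exons$strand[1],
    start = seg_start, end = seg_end,
    count = lengths(covering),
    kind = ifelse(lengths(covering) > 0, "unit", "gap"),
    covering = covering)
  ## maximality: adjacent segments must differ in covering set (holds by
  ## construction because every boundary is an exon endpoint and abutting
  ## exons within a transcript are merged on read)
  class(segs) <- c("ase_segments", class(segs))
  segs
}

#' Format a segment profile's count string
#'
#' @param segments Result of [flatten_units()].
#' @return A string such as `"[2-0-1-0-2]"`.
#' @export
count_string <- function(segments) {
  paste0("[", paste(segments$count, collapse = "-"), "]")
}

#' Detect cassette-exon events within one gene group
#'
#' An event is emitted for every exon trio (5' flank, cassette, 3' flank)
#' such that at least one isoform's exon chain contains the three exons
#' consecutively and exactly, and at least one other isoform's chain
#' joins the two flanks by a direct junction (two consecutive exons
#' exactly equal to the flanks).  Flank coordinates must match exactly on
#' both boundaries; terminal exons may serve as flanks but never as the
#' cassette.  For a two-isoform gene this reduces to the `[2-0-1-0-2]`
#' count-string pattern over the trio window.  The including/skipping
#' sets record every isoform carrying the respective chain; duplicate
#' trios are emitted once.
#'
#' @param gene_exons Exon-level tibble for a single gene group.
#' @return A cassette-event tibble (possibly empty).
#' @export
detect_cassette_events <- function(gene_exons) {
  validate_transcripts(gene_exons)
  if (nrow(gene_exons) == 0) return(empty_events())
  if (dplyr::n_distinct(gene_exons$chrom) != 1 ||
      dplyr::n_distinct(gene_exons$strand) != 1) {
    abort("detect_cassette_events() expects a single gene group",
          class = "altevents_validation_error")
  }
  ex <- gene_exons |> arrange(.data$transcript_id, .data$start)
  chains <- split(ex[c("start", "end")], ex$transcript_id)
  pairs <- purrr::imap(chains, function(ch, tid) {
    n <- nrow(ch)
    if (n < 2) return(NULL)
    tibble(transcript_id = tid,
           p1s = ch$start[-n], p1e = ch$end[-n],
           p2s = ch$start[-1], p2e = ch$end[-1])
  }) |> bind_rows()
  trios <- purrr::imap(chains, function(ch, tid) {
    n <- nrow(ch)
    if (n < 3) return(NULL)
    i <- seq_len(n - 2)
    tibble(transcript_id = tid,
           s1 = ch$start[i], e1 = ch$end[i],
           s2 = ch$start[i + 1], e2 = ch$end[i + 1],
           s3 = ch$start[i + 2], e3 = ch$end[i + 2])
  }) |> bind_rows()
  if (nrow(pairs) == 0 || nrow(trios) == 0) return(empty_events())
  trio_sets <- trios |>
    group_by(.data$s1, .data$e1, .data$s2, .data$e2, .data$s3, .data$e3) |>
    summarise(including = join_ids(.data$transcript_id), .groups = "drop")
  pair_sets <- pairs |>
    group_by(.data$p1s, .data$p1e, .data$p2s, .data$p2e) |>
    summarise(skipping = join_ids(.data$transcript_id), .groups = "drop")
  hits <- inner_join(trio_sets, pair_sets,
                     by = c(s1 = "p1s", e1 = "p1e", s3 = "p2s", e3 = "p2e"))
  if (nrow(hits) == 0) return(empty_events())
  new_events(chrom = gene_exons$chrom[1], strand = gene_exons$strand[1],
             left_start = hits$s1, left_end = hits$e1,
             mid_start = hits$s2, mid_end = hits$e2,
             right_start = hits$s3, right_end = hits$e3,
             including = hits$including, skipping = hits$skipping)
}

#' Find cassette-exon events across an annotation
#'
#' Composes [group_transcripts()] and [detect_cassette_events()] over
#' every gene group, deduplicates events globally by event id (isoform
#' sets are unioned when the same trio arises from more than one group),
#' and returns a deterministically sorted event table.
#'
#' @param transcripts Exon-level transcript tibble, e.g. from
#'   [read_gtf()] or [read_bed12()].
#' @return A cassette-event tibble.
#' @export
find_events <- function(transcripts) {
  grouped <- group_transcripts(transcripts)
  if (nrow(grouped) == 0) return(empty_events())
  events <- grouped |>
    dplyr::group_split(.data$gene_id, .data$chrom, .data$strand) |>
    purrr::map(detect_cassette_events) |>
    bind_rows()
  if (nrow(events) == 0) return(empty_events())
  events |>
    group_by(dplyr::across(dplyr::all_of(setdiff(event_cols,
                                                 c("including", "skipping"))))) |>
    summarise(
      including = join_ids(unlist(lapply(.data$including, split_ids))),
      skipping = join_ids(unlist(lapply(.data$skipping, split_ids))),
      .groups = "drop") |>
    select(dplyr::all_of(event_cols)) |>
    arrange_events()
}
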