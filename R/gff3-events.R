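#' Write cassette events as MISO-consumable GFF3
#'
#' Serializes each event as a three-level hierarchy: one `gene` record
#' spanning the trio, two `mRNA` children — the canonical inclusion form
#' with three exons and the canonical exclusion form with two — and
#' `exon` grandchildren.  Exactly two mRNAs are emitted per event
#' regardless of how many source isoforms supported each form, matching
#' the two-isoform event model of downstream quantifiers; the supporting
#' transcript ids are carried in an `isoforms=` attribute on each mRNA.
#' Coordinates are 1-based inclusive; events are ordered by chromosome,
#' trio start, then event id.
#'
#' @param events Cassette-event tibble (see [find_events()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gff3_events <- function(events, path) {
  validate_events(events)
  header <- "##gff-version 3"
  if (nrow(events) == 0) return(write_lines_atomic(header, path))
  ev <- arrange_events(events)
  recs <- purrr::pmap(ev, function(event_id, chrom, strand,
                                   flank5_start, flank5_end,
                                   cassette_start, cassette_end,
                                   flank3_start, flank3_end,
                                   including, skipping, ...) {
    gene_start <- min(flank5_start, flank3_start) + 1L
    gene_end <- max(flank5_end, flank3_end)
    inc_id <- paste0(event_id, ".A")
    exc_id <- paste0(event_id, ".B")
    ## exon trio in ascending genome order
    starts <- sort(c(flank5_start, cassette_start, flank3_start)) + 1L
    ends <- sort(c(flank5_end, cassette_end, flank3_end))
    line <- function(type, s, e, attrs) {
      sprintf("%s\taltevents\t%s\t%d\t%d\t.\t%s\t.\t%s",
              chrom, type, s, e, strand, attrs)
    }
    c(line("gene", gene_start, gene_end,
           sprintf("ID=%s;Name=%s", event_id, event_id)),
      line("mRNA", gene_start, gene_end,
           sprintf("ID=%s;Parent=%s;isoforms=%s", inc_id, event_id, including)),
      line("exon", starts[1], ends[1],
           sprintf("ID=%s.ex1;Parent=%s", inc_id, inc_id)),
      line("exon", starts[2], ends[2],
           sprintf("ID=%s.ex2;Parent=%s", inc_id, inc_id)),
      line("exon", starts[3], ends[3],
           sprintf("ID=%s.ex3;Parent=%s", inc_id, inc_id)),
      line("mRNA", gene_start, gene_end,
           sprintf("ID=%s;Parent=%s;isoforms=%s", exc_id, event_id, skipping)),
      line("exon", starts[1], ends[1],
           sprintf("ID=%s.ex1;Parent=%s", exc_id, exc_id)),
      line("exon", starts[3], ends[3],
           sprintf("ID=%s.ex2;Parent=%s", exc_id, exc_id)))
  })
  write_lines_atomic(c(header, unlist(recs)), path)
}

#' Read cassette events from GFF3
#'
#' Reads the gene/mRNA/exon event dialect written by
#' [write_gff3_events()].  The trio is reconstructed from the three-exon
#' mRNA (the middle exon is the cassette; flanks are labeled 5'/3' by
#' strand) and the isoform-id sets from the `isoforms=` attributes (the
#' mRNA `ID` is used when the attribute is absent).  Gene records whose
#' mRNA children do not have exactly {3, 2} exon counts, or whose
#' exclusion exons do not match the inclusion flanks, are skipped with a
#' warning, tolerating foreign records in third-party event libraries;
#' the number skipped is attached as attribute `n_skipped`.
#'
#' @param path Path to a GFF3 event annotation.
#' @return A cassette-event tibble with attribute `n_skipped`.
#' @export
read_gff3_events <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "altevents_io_error")
  }
  lines <- readr::read_lines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  out <- empty_events()
  if (length(idx) == 0) {
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- idx[which(nf != 9L)[1]]
    abort(sprintf("GFF3 parse error at line %d: expected 9 fields, got %d",
                  bad, nf[which(nf != 9L)[1]]),
          class = "altevents_parse_error")
  }
  m <- do.call(rbind, fields)
  recs <- tibble(
    chrom = m[, 1], type = m[, 3],
    start = suppressWarnings(as.integer(m[, 4])) - 1L,
    end = suppressWarnings(as.integer(m[, 5])),
    strand = m[, 7],
    id = gff3_attr(m[, 9], "ID"),
    parent = gff3_attr(m[, 9], "Parent"),
    isoforms = gff3_attr(m[, 9], "isoforms"))
  if (anyNA(recs$start) || anyNA(recs$end)) {
    abort("GFF3 parse error: non-integer coordinates",
          class = "altevents_parse_error")
  }
  genes <- recs[recs$type == "gene", , drop = FALSE]
  mrnas <- recs[recs$type == "mRNA", , drop = FALSE]
  exons <- recs[recs$type == "exon", , drop = FALSE]
  n_skipped <- 0L
  rows <- vector("list", nrow(genes))
  for (g in seq_len(nrow(genes))) {
    gid <- genes$id[g]
    kids <- mrnas[!is.na(mrnas$parent) & mrnas$parent == gid, , drop = FALSE]
    kid_exons <- lapply(kids$id, function(mid) {
      ex <- exons[!is.na(exons$parent) & exons$parent == mid, , drop = FALSE]
      ex[order(ex$start), , drop = FALSE]
    })
    n_ex <- vapply(kid_exons, nrow, integer(1))
    if (nrow(kids) != 2L || !setequal(n_ex, c(3L, 2L)) ||
        !genes$strand[g] %in% c("+", "-")) {
      n_skipped <- n_skipped + 1L
      next
    }
    inc <- kid_exons[[which(n_ex == 3L)]]
    exc <- kid_exons[[which(n_ex == 2L)]]
    if (!identical(exc$start, inc$start[c(1L, 3L)]) ||
        !identical(exc$end, inc$end[c(1L, 3L)])) {
      n_skipped <- n_skipped + 1L
      next
    }
    inc_iso <- kids$isoforms[which(n_ex == 3L)] %|NA|% kids$id[which(n_ex == 3L)]
    exc_iso <- kids$isoforms[which(n_ex == 2L)] %|NA|% kids$id[which(n_ex == 2L)]
    rows[[g]] <- new_events(
      chrom = genes$chrom[g], strand = genes$strand[g],
      left_start = inc$start[1], left_end = inc$end[1],
      mid_start = inc$start[2], mid_end = inc$end[2],
      right_start = inc$start[3], right_end = inc$end[3],
      including = join_ids(split_ids(inc_iso)),
      skipping = join_ids(split_ids(exc_iso)))
  }
  if (n_skipped > 0) {
    warn(sprintf("skipped %d gene record(s) not matching the {3,2}-exon event dialect in %s",
                 n_skipped, path))
  }
  out <- arrange_events(bind_rows(c(list(empty_events()), rows)))
  attr(out, "n_skipped") <- n_skipped
  out
}

gff3_attr <- function(attrs, key) {
  v <- stringr::str_match(attrs, paste0("(?:^|;)\\s*", key, "=([^;]*)"))[, 2]
  v
}

`%|NA|%` <- function(a, b) if (is.na(a) || a == "") b else a
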