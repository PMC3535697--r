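## Cassette-event table construction and validation.

## Event id encodes the trio loci and strand, 1-based inclusive, in
## transcription order: chrom:f5s-f5e@cs-ce@f3s-f3e:strand.  Unique per
## trio and human-readable.
make_event_id <- function(chrom, strand, f5s, f5e, cs, ce, f3s, f3e) {
  sprintf("%s:%d-%d@%d-%d@%d-%d:%s",
          chrom, f5s + 1L, f5e, cs + 1L, ce, f3s + 1L, f3e, strand)
}

## Build an event tibble from genome-ordered trios (left < mid < right).
## The 5' flank is the left exon on '+' and the right exon on '-'.
new_events <- function(chrom, strand, left_start, left_end,
                       mid_start, mid_end, right_start, right_end,
                       including, skipping) {
  n <- length(mid_start)
  plus <- rep_len(strand == "+", n)
  chrom <- rep_len(chrom, n)
  strand <- rep_len(strand, n)
  f5s <- ifelse(plus, left_start, right_start)
  f5e <- ifelse(plus, left_end, right_end)
  f3s <- ifelse(plus, right_start, left_start)
  f3e <- ifelse(plus, right_end, left_end)
  ev <- tibble(
    event_id = make_event_id(chrom, strand, f5s, f5e, mid_start, mid_end,
                             f3s, f3e),
    chrom = chrom, strand = strand,
    flank5_start = as.integer(f5s), flank5_end = as.integer(f5e),
    cassette_start = as.integer(mid_start), cassette_end = as.integer(mid_end),
    flank3_start = as.integer(f3s), flank3_end = as.integer(f3e),
    including = including, skipping = skipping)
  arrange_events(ev)
}

genome_left_start <- function(events) {
  pmin(events$flank5_start, events$flank3_start)
}

arrange_events <- function(events) {
  events |>
    mutate(.left = genome_left_start(events)) |>
    arrange(.data$chrom, .data$.left, .data$cassette_start, .data$event_id) |>
    select(-".left")
}

#' Validate a cassette-event table
#'
#' Checks the event invariants: required columns, intervals non-empty and
#' mutually non-overlapping, genome-contiguous trio ordering consistent
#' with the strand (on `+` the 5' flank precedes the cassette which
#' precedes the 3' flank; on `-` the genome order is reversed), and
#' including/skipping isoform sets non-empty and disjoint.
#'
#' @param events Cassette-event tibble.
#' @return The input, invisibly, in canonical order.
#' @export
validate_events <- function(events) {
  missing <- setdiff(event_cols, names(events))
  if (length(missing) > 0) {
    abort(sprintf("event table lacks column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "altevents_validation_error")
  }
  if (nrow(events) == 0) return(invisible(empty_events()))
  with(events, {
    if (any(!strand %in% c("+", "-"))) {
      abort("event strand must be '+' or '-'", class = "altevents_validation_error")
    }
    ok_len <- flank5_start < flank5_end & cassette_start < cassette_end &
      flank3_start < flank3_end
    plus <- strand == "+"
    ok_order <- ifelse(plus,
                       flank5_end <= cassette_start & cassette_end <= flank3_start,
                       flank3_end <= cassette_start & cassette_end <= flank5_start)
    if (any(!ok_len | !ok_order)) {
      abort(sprintf("malformed trio geometry for event(s): %s",
                    paste(events$event_id[!ok_len | !ok_order], collapse = ", ")),
            class = "altevents_validation_error")
    }
  })
  inc <- lapply(events$including, split_ids)
  skp <- lapply(events$skipping, split_ids)
  bad <- lengths(inc) == 0 | lengths(skp) == 0 |
    purrr::map2_lgl(inc, skp, ~ length(intersect(.x, .y)) > 0)
  if (any(bad)) {
    abort(sprintf(
      "including/skipping isoform sets must be non-empty and disjoint: %s",
      paste(events$event_id[bad], collapse = ", ")),
      class = "altevents_validation_error")
  }
  invisible(arrange_events(events))
}
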