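#' Validate an exon-level transcript table
#'
#' Checks the structural invariants of the internal transcript
#' representation: required columns, 0-based half-open intervals with
#' `start < end`, strand in `+`/`-`, one chromosome and strand per
#' transcript, at least one exon per transcript, and exons strictly
#' non-overlapping with at least one intronic base between neighbours
#' (abutting blocks are merged by the readers, never stored).
#'
#' @param transcripts A tibble with columns `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `start`, `end` (one row per exon).
#' @return The input, invisibly, arranged in canonical order
#'   (chrom, transcript span start, transcript_id, exon start).
#' @export
validate_transcripts <- function(transcripts) {
  missing <- setdiff(transcript_cols, names(transcripts))
  if (length(missing) > 0) {
    abort(sprintf("transcript table lacks column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "altevents_validation_error")
  }
  if (nrow(transcripts) == 0) return(invisible(empty_transcripts()))
  if (any(is.na(transcripts$start)) || any(is.na(transcripts$end)) ||
      any(transcripts$start >= transcripts$end)) {
    abort("exon intervals must satisfy start < end with no missing values",
          class = "altevents_validation_error")
  }
  if (any(!transcripts$strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-' for every exon",
          class = "altevents_validation_error")
  }
  if (any(is.na(transcripts$chrom)) || any(transcripts$chrom == "")) {
    abort("chrom must be non-empty", class = "altevents_validation_error")
  }
  per_tx <- transcripts |>
    group_by(.data$transcript_id) |>
    summarise(n_chrom = dplyr::n_distinct(.data$chrom),
              n_strand = dplyr::n_distinct(.data$strand),
              n_gene = dplyr::n_distinct(.data$gene_id),
              .groups = "drop")
  bad <- per_tx$transcript_id[per_tx$n_chrom > 1 | per_tx$n_strand > 1 |
                                per_tx$n_gene > 1]
  if (length(bad) > 0) {
    abort(sprintf(
      "transcript(s) with exons on multiple chromosomes/strands or gene ids: %s",
      paste(bad, collapse = ", ")), class = "altevents_validation_error")
  }
  ord <- transcripts |>
    arrange(.data$transcript_id, .data$start)
  same_tx <- ord$transcript_id[-1] == ord$transcript_id[-nrow(ord)]
  gap_ok <- ord$start[-1] > ord$end[-nrow(ord)]
  if (any(same_tx & !gap_ok)) {
    bad_tx <- unique(ord$transcript_id[-1][same_tx & !gap_ok])
    abort(sprintf("overlapping or abutting exons within transcript(s): %s",
                  paste(bad_tx, collapse = ", ")),
          class = "altevents_validation_error")
  }
  invisible(arrange_transcripts(transcripts))
}

## Canonical deterministic ordering for transcript tables.
arrange_transcripts <- function(transcripts) {
  if (nrow(transcripts) == 0) return(transcripts)
  spans <- transcripts |>
    group_by(.data$transcript_id) |>
    summarise(.tx_start = min(.data$start), .groups = "drop")
  transcripts |>
    left_join(spans, by = "transcript_id") |>
    arrange(.data$chrom, .data$.tx_start, .data$transcript_id, .data$start) |>
    select(-".tx_start")
}

## Merge abutting exon blocks (zero-length introns) within each transcript.
## Assembler outputs occasionally contain them; downstream segmentation
## assumes real introns.  Exons must already be sorted within transcripts.
merge_abutting <- function(transcripts) {
  if (nrow(transcripts) == 0) return(transcripts)
  transcripts |>
    arrange(.data$transcript_id, .data$start) |>
    group_by(.data$transcript_id) |>
    mutate(.run = cumsum(c(1L, as.integer(.data$start[-1] > .data$end[-n()])))) |>
    group_by(.data$transcript_id, .data$gene_id, .data$chrom, .data$strand,
             .data$.run) |>
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop") |>
    select(dplyr::all_of(transcript_cols))
}
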