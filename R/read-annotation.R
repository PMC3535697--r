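#' Read transcript models from a Cufflinks-style GTF file
#'
#' Consumes `exon` features only, groups them by the `transcript_id`
#' attribute and carries the `gene_id` attribute through.  GTF 1-based
#' inclusive coordinates are converted to the internal 0-based half-open
#' convention.  Comment lines (`#`) are skipped, non-`exon` features
#' ignored, exons sorted by coordinate, and abutting exon records
#' (zero-length introns) merged.
#'
#' @param path Path to a GTF file.
#' @return An exon-level tibble with columns `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `start`, `end` (one row per exon), in canonical
#'   order.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "altevents_io_error")
  }
  lines <- readr::read_lines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) return(empty_transcripts())
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- idx[which(nf != 9L)[1]]
    abort(sprintf("GTF parse error at line %d: expected 9 tab-separated fields, got %d",
                  bad, nf[which(nf != 9L)[1]]),
          class = "altevents_parse_error")
  }
  m <- do.call(rbind, fields)
  is_exon <- m[, 3] == "exon"
  if (!any(is_exon)) return(empty_transcripts())
  m <- m[is_exon, , drop = FALSE]
  exon_lines <- idx[is_exon]
  start1 <- suppressWarnings(as.integer(m[, 4]))
  end1 <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(start1) || anyNA(end1)) {
    bad <- exon_lines[which(is.na(start1) | is.na(end1))[1]]
    abort(sprintf("GTF parse error at line %d: non-integer coordinates", bad),
          class = "altevents_parse_error")
  }
  tx <- stringr::str_match(m[, 9], 'transcript_id\\s+"([^"]*)"')[, 2]
  if (anyNA(tx) || any(tx == "")) {
    bad <- exon_lines[which(is.na(tx) | tx == "")[1]]
    abort(sprintf("GTF parse error at line %d: missing transcript_id attribute", bad),
          class = "altevents_parse_error")
  }
  gene <- stringr::str_match(m[, 9], 'gene_id\\s+"([^"]*)"')[, 2]
  gene[is.na(gene)] <- ""
  out <- tibble(transcript_id = tx, gene_id = gene,
                chrom = m[, 1], strand = m[, 7],
                start = start1 - 1L, end = end1)
  finalize_models(out, what = "GTF")
}

#' Read transcript models from a Scripture-style BED12 file
#'
#' Each 12-column line becomes one transcript; exon intervals are
#' reconstructed from `chromStart + blockStarts[i]` with `blockSizes[i]`
#' lengths (BED is already 0-based half-open).  The `name` column becomes
#' the transcript id; `gene_id` is left empty for later grouping by
#' [group_transcripts()].  Abutting blocks are merged; strandless records
#' are rejected because 5'/3' flank labeling is undefined without strand.
#'
#' @param path Path to a BED12 file.
#' @return An exon-level tibble (see [read_gtf()]); `gene_id` is `""`.
#' @export
read_bed12 <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "altevents_io_error")
  }
  lines <- readr::read_lines(path)
  keep <- !grepl("^\\s*(#|track|browser|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) return(empty_transcripts())
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- idx[which(nf != 12L)[1]]
    abort(sprintf("BED12 parse error at line %d: expected 12 fields, got %d",
                  bad, nf[which(nf != 12L)[1]]),
          class = "altevents_parse_error")
  }
  rows <- purrr::map2(fields, idx, function(f, ln) {
    chrom_start <- suppressWarnings(as.integer(f[2]))
    n_blocks <- suppressWarnings(as.integer(f[10]))
    if (is.na(chrom_start) || is.na(n_blocks)) {
      abort(sprintf("BED12 parse error at line %d: non-integer coordinates", ln),
            class = "altevents_parse_error")
    }
    sizes <- parse_block_list(f[11], ln)
    starts <- parse_block_list(f[12], ln)
    if (length(sizes) != n_blocks || length(starts) != n_blocks) {
      abort(sprintf(
        "BED12 parse error at line %d: blockCount %d does not match blockSizes/blockStarts lengths (%d/%d)",
        ln, n_blocks, length(sizes), length(starts)),
        class = "altevents_parse_error")
    }
    if (!f[6] %in% c("+", "-")) {
      abort(sprintf(
        "BED12 validation error at line %d: strand '%s' (strandless records are rejected)",
        ln, f[6]), class = "altevents_validation_error")
    }
    tibble(transcript_id = f[4], gene_id = "",
           chrom = f[1], strand = f[6],
           start = chrom_start + starts,
           end = chrom_start + starts + sizes)
  })
  finalize_models(bind_rows(rows), what = "BED12")
}

parse_block_list <- function(x, line) {
  x <- sub(",+$", "", x)
  if (x == "") {
    abort(sprintf("BED12 parse error at line %d: empty block list", line),
          class = "altevents_parse_error")
  }
  v <- suppressWarnings(as.integer(strsplit(x, ",", fixed = TRUE)[[1]]))
  if (anyNA(v)) {
    abort(sprintf("BED12 parse error at line %d: non-integer block list", line),
          class = "altevents_parse_error")
  }
  v
}

## Shared tail of both readers: reject strand other than +/-, reject
## transcripts spanning chromosomes/strands, error on overlapping exons,
## merge abutting blocks, validate, and order canonically.
finalize_models <- function(exons, what) {
  if (nrow(exons) == 0) return(empty_transcripts())
  if (any(!exons$strand %in% c("+", "-"))) {
    bad <- unique(exons$transcript_id[!exons$strand %in% c("+", "-")])
    abort(sprintf("%s validation error: strand must be '+' or '-' for transcript(s): %s",
                  what, paste(bad, collapse = ", ")),
          class = "altevents_validation_error")
  }
  if (any(exons$start >= exons$end)) {
    bad <- unique(exons$transcript_id[exons$start >= exons$end])
    abort(sprintf("%s validation error: empty or inverted exon in transcript(s): %s",
                  what, paste(bad, collapse = ", ")),
          class = "altevents_validation_error")
  }
  per_tx <- exons |>
    group_by(.data$transcript_id) |>
    summarise(n_chrom = dplyr::n_distinct(.data$chrom),
              n_strand = dplyr::n_distinct(.data$strand), .groups = "drop")
  bad <- per_tx$transcript_id[per_tx$n_chrom > 1 | per_tx$n_strand > 1]
  if (length(bad) > 0) {
    abort(sprintf("%s validation error: transcript(s) on multiple chromosomes or strands: %s",
                  what, paste(bad, collapse = ", ")),
          class = "altevents_validation_error")
  }
  sorted <- exons |> arrange(.data$transcript_id, .data$start)
  same_tx <- sorted$transcript_id[-1] == sorted$transcript_id[-nrow(sorted)]
  overlaps <- sorted$start[-1] < sorted$end[-nrow(sorted)]
  if (any(same_tx & overlaps)) {
    bad <- unique(sorted$transcript_id[-1][same_tx & overlaps])
    abort(sprintf("%s validation error: overlapping exons within transcript(s): %s",
                  what, paste(bad, collapse = ", ")),
          class = "altevents_validation_error")
  }
  merged <- merge_abutting(sorted)
  validate_transcripts(merged)
  arrange_transcripts(merged)
}

#' Write transcript models as GTF
#'
#' Emits one `exon` feature per exon with `gene_id`/`transcript_id`
#' attributes, 1-based inclusive coordinates, in canonical deterministic
#' order.  Primarily used to serialize synthetic annotations.
#'
#' @param transcripts Exon-level transcript tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gtf <- function(transcripts, path) {
  validate_transcripts(transcripts)
  tx <- arrange_transcripts(transcripts)
  lines <- sprintf(
    '%s\taltevents\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    tx$chrom, tx$start + 1L, tx$end, tx$strand, tx$gene_id, tx$transcript_id)
  write_lines_atomic(lines, path)
}

#' Write transcript models as BED12
#'
#' One line per transcript with block-encoded exons.  The `gene_id` is not
#' representable in BED12 and is dropped; [group_transcripts()] recovers
#' gene grouping by exonic overlap after reading.
#'
#' @inheritParams write_gtf
#' @return The path, invisibly.
#' @export
write_bed12 <- function(transcripts, path) {
  validate_transcripts(transcripts)
  tx <- arrange_transcripts(transcripts)
  if (nrow(tx) == 0) return(write_lines_atomic(character(), path))
  per <- tx |>
    group_by(.data$transcript_id, .data$chrom, .data$strand) |>
    summarise(chrom_start = min(.data$start), chrom_end = max(.data$end),
              sizes = paste(.data$end - .data$start, collapse = ","),
              rel_starts = paste(.data$start - min(.data$start), collapse = ","),
              n_blocks = n(), .groups = "drop") |>
    arrange(.data$chrom, .data$chrom_start, .data$transcript_id)
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
                   per$chrom, per$chrom_start, per$chrom_end,
                   per$transcript_id, per$strand,
                   per$chrom_start, per$chrom_end,
                   per$n_blocks, per$sizes, per$rel_starts)
  write_lines_atomic(lines, path)
}
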