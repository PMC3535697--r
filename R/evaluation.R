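#' Match data-driven events against a known event library
#'
#' An event pair matches only if chromosome, strand and the genomic loci
#' of all three exons — the cassette and its 5' and 3' flanks — are
#' identical; no partial or overlap-based matching is performed, giving
#' the most conservative comparison.  Both inputs are deduplicated by
#' event id first, so matching is one-to-one.
#'
#' @param data Cassette-event tibble derived from the data.
#' @param known Cassette-event tibble of the known library.
#' @return A tibble with one row per match: `data_event_id`,
#'   `known_event_id` and the shared trio coordinates.
#' @export
match_events <- function(data, known) {
  validate_events(data)
  validate_events(known)
  key <- setdiff(event_cols, c("event_id", "including", "skipping"))
  d <- data |> distinct(.data$event_id, .keep_all = TRUE) |>
    select(data_event_id = "event_id", dplyr::all_of(key))
  k <- known |> distinct(.data$event_id, .keep_all = TRUE) |>
    select(known_event_id = "event_id", dplyr::all_of(key))
  inner_join(d, k, by = key) |>
    select("data_event_id", "known_event_id", dplyr::all_of(key))
}

#' Compute rate-of-known-events and recall
#'
#' The rate of known events (RKE) is the number of matched events divided
#' by the number of data-driven events; recall is the number of matched
#' events divided by the number of events in the known library.  Both
#' inputs are deduplicated by event id.  An empty denominator yields an
#' `NA` metric with a warning, never 0.
#'
#' @inheritParams match_events
#' @return An object of class `ase_metrics`: a list with elements
#'   `n_data`, `n_known`, `n_overlap`, `rke`, `recall`.  Use [tidy()] /
#'   [glance()] for tibble views and [write_metrics()] to serialize.
#' @export
compute_metrics <- function(data, known) {
  matches <- match_events(data, known)
  n_data <- dplyr::n_distinct(data$event_id)
  n_known <- dplyr::n_distinct(known$event_id)
  n_overlap <- nrow(matches)
  rke <- if (n_data > 0) n_overlap / n_data else {
    warn("no data-driven events: rate of known events is undefined")
    NA_real_
  }
  recall <- if (n_known > 0) n_overlap / n_known else {
    warn("no known events: recall is undefined")
    NA_real_
  }
  structure(list(n_data = n_data, n_known = n_known, n_overlap = n_overlap,
                 rke = rke, recall = recall),
            class = "ase_metrics")
}

#' @export
print.ase_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.4f", v)
  cat("Cassette-event evaluation\n",
      sprintf("  data-driven events : %d\n", x$n_data),
      sprintf("  known-library events: %d\n", x$n_known),
      sprintf("  overlapping events : %d\n", x$n_overlap),
      sprintf("  rate of known events (RKE): %s\n", fmt(x$rke)),
      sprintf("  recall             : %s\n", fmt(x$recall)), sep = "")
  invisible(x)
}

#' @importFrom broom tidy
#' @export
broom::tidy

#' @importFrom broom glance
#' @export
broom::glance

#' Tidy an evaluation result
#'
#' @param x An `ase_metrics` object.
#' @param ... Unused.
#' @return One row per metric with columns `metric`, `value`.
#' @method tidy ase_metrics
#' @export
tidy.ase_metrics <- function(x, ...) {
  tibble(metric = c("n_data", "n_known", "n_overlap", "rke", "recall"),
         value = c(x$n_data, x$n_known, x$n_overlap, x$rke, x$recall))
}

#' One-row summary of an evaluation result
#'
#' @inheritParams tidy.ase_metrics
#' @return A one-row tibble with columns `n_data`, `n_known`,
#'   `n_overlap`, `rke`, `recall`.
#' @method glance ase_metrics
#' @export
glance.ase_metrics <- function(x, ...) {
  tibble(n_data = x$n_data, n_known = x$n_known, n_overlap = x$n_overlap,
         rke = x$rke, recall = x$recall)
}

#' Write an evaluation result as TSV
#'
#' @param metrics An `ase_metrics` object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  g <- glance(metrics)
  lines <- c(paste(names(g), collapse = "\t"),
             paste(vapply(g, function(v) {
               if (is.na(v)) "NA" else format(v, scientific = FALSE)
             }, character(1)), collapse = "\t"))
  write_lines_atomic(lines, path)
}

#' Read a read-support side table
#'
#' A headered TSV with columns `event_id`, `inclusion_reads`,
#' `exclusion_reads` — junction/exonic read counts supporting the
#' cassette-containing form and the flank–flank skipping junction,
#' typically exported from a downstream quantifier.
#'
#' @param path Path to the TSV.
#' @return A tibble with the three columns.
#' @export
read_support_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "altevents_io_error")
  }
  tab <- readr::read_tsv(path, col_types = readr::cols(
    event_id = readr::col_character(),
    inclusion_reads = readr::col_integer(),
    exclusion_reads = readr::col_integer()))
  missing <- setdiff(c("event_id", "inclusion_reads", "exclusion_reads"),
                     names(tab))
  if (length(missing) > 0) {
    abort(sprintf("support table lacks column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "altevents_parse_error")
  }
  tab
}

#' Filter events by read support
#'
#' Retains exactly the events with at least `min_inclusion` reads
#' supporting the inclusion form and at least `min_exclusion` reads
#' supporting the exclusion form (defaults 10 and 1).  Events without a
#' support record are treated as having zero support on both sides.
#'
#' @param events Cassette-event tibble.
#' @param support Tibble with columns `event_id`, `inclusion_reads`,
#'   `exclusion_reads`; one row per event id.
#' @param min_inclusion,min_exclusion Non-negative thresholds, inclusive.
#' @return The retained events, in canonical order.
#' @export
filter_by_read_support <- function(events, support = NULL,
                                   min_inclusion = 10L, min_exclusion = 1L) {
  validate_events(events)
  if (min_inclusion < 0 || min_exclusion < 0) {
    abort("thresholds must be non-negative", class = "altevents_validation_error")
  }
  if (is.null(support)) {
    support <- tibble(event_id = character(), inclusion_reads = integer(),
                      exclusion_reads = integer())
  }
  if (anyDuplicated(support$event_id)) {
    abort(sprintf("duplicate event_id in support table: %s",
                  paste(unique(support$event_id[duplicated(support$event_id)]),
                        collapse = ", ")),
          class = "altevents_validation_error")
  }
  if (any(support$inclusion_reads < 0) || any(support$exclusion_reads < 0)) {
    abort("read counts must be non-negative", class = "altevents_validation_error")
  }
  events |>
    left_join(support, by = "event_id") |>
    mutate(inclusion_reads = dplyr::coalesce(.data$inclusion_reads, 0L),
           exclusion_reads = dplyr::coalesce(.data$exclusion_reads, 0L)) |>
    filter(.data$inclusion_reads >= min_inclusion,
           .data$exclusion_reads >= min_exclusion) |>
    select(dplyr::all_of(event_cols)) |>
    arrange_events()
}
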