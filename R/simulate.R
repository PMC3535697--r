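#' Configure the synthetic annotation generator
#'
#' Builds a validated configuration for [generate_annotation()].  The
#' generator lays non-overlapping multi-isoform gene models onto
#' synthetic chromosomes (`synth1`, `synth2`, ...) and plants cassette
#' events with known truth; the remaining genes are decoys (single
#' isoform, identical isoform copies, alternative first/last exon
#' boundaries, or flank-boundary shifts on a skipped form) that must not
#' be called as cassettes.
#'
#' @param n_genes Number of genes to generate.
#' @param cassette_fraction Probability that a gene carries one planted
#'   cassette event.
#' @param isoforms_per_gene Integer range `c(lo, hi)` of isoforms per
#'   gene (cassette genes always get at least the inclusion and skipping
#'   forms).
#' @param exons_per_isoform Integer range of exons per isoform; cassette
#'   genes need at least 3.
#' @param exon_length,intron_length Integer ranges in bp.
#' @param strand_probability Probability of the `+` strand.
#' @param gene_spacing Intergenic gap in bp.
#' @param genes_per_chrom Genes placed per synthetic chromosome.
#' @param seed Integer random seed; the generator is fully deterministic
#'   given the seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 50, cassette_fraction = 0.4,
                       isoforms_per_gene = c(2L, 3L),
                       exons_per_isoform = c(3L, 8L),
                       exon_length = c(50L, 300L),
                       intron_length = c(200L, 5000L),
                       strand_probability = 0.5,
                       gene_spacing = 10000L,
                       genes_per_chrom = 10L,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              cassette_fraction = cassette_fraction,
              isoforms_per_gene = as.integer(isoforms_per_gene),
              exons_per_isoform = as.integer(exons_per_isoform),
              exon_length = as.integer(exon_length),
              intron_length = as.integer(intron_length),
              strand_probability = strand_probability,
              gene_spacing = as.integer(gene_spacing),
              genes_per_chrom = as.integer(genes_per_chrom),
              seed = as.integer(seed))
  bad_range <- function(r, lo_min) {
    length(r) != 2 || anyNA(r) || r[1] > r[2] || r[1] < lo_min
  }
  if (is.na(cfg$n_genes) || cfg$n_genes < 0) {
    abort("n_genes must be a non-negative integer", class = "altevents_config_error")
  }
  if (cfg$cassette_fraction < 0 || cfg$cassette_fraction > 1 ||
      cfg$strand_probability < 0 || cfg$strand_probability > 1) {
    abort("probabilities must lie in [0, 1]", class = "altevents_config_error")
  }
  if (bad_range(cfg$isoforms_per_gene, 1L)) {
    abort("isoforms_per_gene must be a non-empty positive range",
          class = "altevents_config_error")
  }
  if (bad_range(cfg$exons_per_isoform, 1L)) {
    abort("exons_per_isoform must be a non-empty positive range",
          class = "altevents_config_error")
  }
  if (bad_range(cfg$exon_length, 2L)) {
    abort("exon_length must be a range with lower bound >= 2 bp",
          class = "altevents_config_error")
  }
  if (bad_range(cfg$intron_length, 1L)) {
    abort("intron_length must be a non-empty positive range",
          class = "altevents_config_error")
  }
  if (cfg$cassette_fraction > 0 && cfg$exons_per_isoform[2] < 3) {
    abort("infeasible config: cassette genes need isoforms with at least 3 exons",
          class = "altevents_config_error")
  }
  if (cfg$cassette_fraction > 0 && cfg$isoforms_per_gene[2] < 2) {
    abort("infeasible config: cassette genes need at least 2 isoforms",
          class = "altevents_config_error")
  }
  if (cfg$gene_spacing < 1 || cfg$genes_per_chrom < 1) {
    abort("gene_spacing and genes_per_chrom must be positive",
          class = "altevents_config_error")
  }
  structure(cfg, class = "sim_config")
}

sample_range <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L)

#' Generate a ground-truthed synthetic annotation
#'
#' Produces transcript models with planted cassette events and decoy
#' structures.  A cassette gene contains one inclusion isoform (chain
#' flank–cassette–flank) and one skipping isoform joining the flanks
#' directly, optionally plus exact copies of either form; decoy genes
#' are single-isoform, multi-isoform with identical chains, or carry
#' alternative first/last exon boundaries or a shifted flank boundary on
#' the skipped form — structures that must not be reported as cassette
#' events.  Every truth event is detectable by construction.  Output is
#' fully deterministic given the configuration seed.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `ase_simulation` with elements `transcripts`
#'   (exon-level tibble), `truth` (list with `events`, a cassette-event
#'   tibble, and `decoys`, the gene ids carrying no event) and `config`.
#' @export
generate_annotation <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  withr::with_seed(config$seed, generate_annotation_impl(config))
}

generate_annotation_impl <- function(cfg) {
  tx_rows <- list()
  truth_rows <- list()
  decoys <- character()
  cursor <- integer()  # per-chromosome next free position
  for (i in seq_len(cfg$n_genes)) {
    chrom <- sprintf("synth%d", (i - 1L) %/% cfg$genes_per_chrom + 1L)
    if (is.na(cursor[chrom])) cursor[chrom] <- cfg$gene_spacing
    strand <- if (runif(1) < cfg$strand_probability) "+" else "-"
    gene_id <- sprintf("SYN%04d", i)
    is_cassette <- runif(1) < cfg$cassette_fraction
    n_exons <- if (is_cassette) {
      sample_range(c(max(3L, cfg$exons_per_isoform[1]), cfg$exons_per_isoform[2]))
    } else {
      sample_range(cfg$exons_per_isoform)
    }
    exon_len <- vapply(seq_len(n_exons), function(...) sample_range(cfg$exon_length),
                       integer(1))
    intron_len <- vapply(seq_len(max(0L, n_exons - 1L)),
                         function(...) sample_range(cfg$intron_length), integer(1))
    starts <- cursor[chrom] + cumsum(c(0L, exon_len[-n_exons] + intron_len))
    ends <- starts + exon_len
    cursor[chrom] <- ends[n_exons] + cfg$gene_spacing
    exon_tbl <- function(tid, idx, s = starts, e = ends) {
      tibble(transcript_id = tid, gene_id = gene_id, chrom = chrom,
             strand = strand, start = s[idx], end = e[idx])
    }
    n_iso <- sample_range(cfg$isoforms_per_gene)
    if (is_cassette) {
      n_iso <- max(2L, n_iso)
      cas <- if (n_exons == 3L) 2L else sample(2:(n_exons - 1L), 1L)
      inc_ids <- character()
      skp_ids <- character()
      gene_rows <- list()
      for (k in seq_len(n_iso)) {
        tid <- sprintf("%s.I%d", gene_id, k)
        if (k %% 2L == 1L) {  # inclusion form (and copies)
          gene_rows[[k]] <- exon_tbl(tid, seq_len(n_exons))
          inc_ids <- c(inc_ids, tid)
        } else {              # skipping form (and copies)
          gene_rows[[k]] <- exon_tbl(tid, setdiff(seq_len(n_exons), cas))
          skp_ids <- c(skp_ids, tid)
        }
      }
      tx_rows[[i]] <- bind_rows(gene_rows)
      truth_rows[[i]] <- new_events(
        chrom = chrom, strand = strand,
        left_start = starts[cas - 1L], left_end = ends[cas - 1L],
        mid_start = starts[cas], mid_end = ends[cas],
        right_start = starts[cas + 1L], right_end = ends[cas + 1L],
        including = join_ids(inc_ids), skipping = join_ids(skp_ids))
    } else {
      decoys <- c(decoys, gene_id)
      classes <- c("identical", "alt_first", "alt_last",
                   if (n_exons >= 3L) "flank_shift")
      class <- if (n_iso == 1L) "single" else sample(classes, 1L)
      t1 <- sprintf("%s.I1", gene_id)
      rows <- list(exon_tbl(t1, seq_len(n_exons)))
      if (class != "single") {
        t2 <- sprintf("%s.I2", gene_id)
        rows[[2]] <- switch(
          class,
          identical = exon_tbl(t2, seq_len(n_exons)),
          alt_first = {  # shifted transcription start within the first exon
            d <- min(10L, exon_len[1] - 1L)
            s2 <- starts; s2[1] <- s2[1] + d
            exon_tbl(t2, seq_len(n_exons), s = s2)
          },
          alt_last = {   # shifted transcription end within the last exon
            d <- min(10L, exon_len[n_exons] - 1L)
            e2 <- ends; e2[n_exons] <- e2[n_exons] - d
            exon_tbl(t2, seq_len(n_exons), e = e2)
          },
          flank_shift = {  # skipped form whose left flank donor is shifted
            cas <- if (n_exons == 3L) 2L else sample(2:(n_exons - 1L), 1L)
            d <- min(7L, exon_len[cas - 1L] - 1L)
            e2 <- ends; e2[cas - 1L] <- e2[cas - 1L] - d
            exon_tbl(t2, setdiff(seq_len(n_exons), cas), e = e2)
          })
        ## further isoforms, if any, are copies of the primary chain
        extra <- seq_len(max(0L, n_iso - 2L))
        rows <- c(rows, lapply(extra, function(k) {
          exon_tbl(sprintf("%s.I%d", gene_id, k + 2L), seq_len(n_exons))
        }))
      }
      tx_rows[[i]] <- bind_rows(rows)
    }
  }
  transcripts <- arrange_transcripts(bind_rows(c(list(empty_transcripts()),
                                                 tx_rows)))
  truth <- arrange_events(bind_rows(c(list(empty_events()), truth_rows)))
  structure(list(transcripts = transcripts,
                 truth = list(events = truth, decoys = decoys),
                 config = cfg),
            class = "ase_simulation")
}

#' Serialize a simulation as a GTF/BED12/GFF3 fixture set
#'
#' Writes the same transcript models as `annotation.gtf` and
#' `annotation.bed`, and the planted truth events as `truth.gff3`.
#'
#' @param sim An `ase_simulation` from [generate_annotation()].
#' @param dir Output directory (created if missing).
#' @return Named character vector with elements `gtf`, `bed`, `truth`.
#' @export
write_fixture_pair <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(gtf = file.path(dir, "annotation.gtf"),
             bed = file.path(dir, "annotation.bed"),
             truth = file.path(dir, "truth.gff3"))
  write_gtf(sim$transcripts, paths[["gtf"]])
  write_bed12(sim$transcripts, paths[["bed"]])
  write_gff3_events(sim$truth$events, paths[["truth"]])
  paths
}

#' Draw a synthetic read-support table for an event set
#'
#' Inclusion and exclusion read counts are drawn independently from
#' Poisson distributions, emulating junction-read tallies from a
#' quantifier.  Intended for exercising [filter_by_read_support()].
#'
#' @param events Cassette-event tibble.
#' @param lambda_inclusion,lambda_exclusion Poisson means for the
#'   inclusion and exclusion counts.
#' @return A support tibble (`event_id`, `inclusion_reads`,
#'   `exclusion_reads`).
#' @export
simulate_read_support <- function(events, lambda_inclusion = 15,
                                  lambda_exclusion = 2) {
  tibble(event_id = events$event_id,
         inclusion_reads = stats::rpois(nrow(events), lambda_inclusion),
         exclusion_reads = stats::rpois(nrow(events), lambda_exclusion))
}
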