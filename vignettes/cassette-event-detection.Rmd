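---
title: "Deriving cassette-exon event annotations from transcript isoform models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving cassette-exon event annotations from transcript isoform models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(altevents)
library(dplyr)
```

## The problem

Transcriptome reconstruction tools such as Cufflinks and Scripture turn
RNA-seq alignments into transcript isoform models, but downstream
quantifiers of alternative splicing (MISO and its relatives) consume
*event* annotations: small local gene models describing, for a cassette
(skipped) exon, the alternative exon together with its 5' and 3'
constitutive flanks in an inclusion and an exclusion form.  Public event
libraries are incomplete, particularly for tissues and conditions that
were not sampled when the library was built, so events present in a new
dataset may simply be absent from the library.  `altevents` closes this
gap: it derives cassette-exon event annotations *de novo* from the
isoform models themselves and writes them as GFF3 that a downstream
quantifier can consume directly.

## The procedure

Detection is purely structural; no reads are consumed.

1. **Gene grouping.** Isoforms sharing a `gene_id` (GTF input) form a
   gene; BED12 input carries no gene ids, so transcripts are clustered
   by single-linkage exonic overlap per chromosome and strand.  Groups
   on opposite strands are never merged, because 5'/3' flank labeling is
   a transcription-order notion.

2. **Minimum non-overlapping exon units.** Within a gene, the union of
   all exons is partitioned at every distinct exon start/end coordinate.
   Each resulting segment is either covered by a constant set of
   isoforms (a *unit*) or by none (a *gap*).  The ordered per-segment
   isoform counts form the gene's *count string*; for a two-isoform gene
   with one skipped exon it reads `[2-0-1-0-2]`.

```{r count-string}
gene <- tibble::tibble(
  transcript_id = rep(c("A", "B"), c(3, 2)), gene_id = "G1",
  chrom = "chr1", strand = "+",
  start = c(0L, 200L, 400L, 0L, 400L),
  end   = c(100L, 300L, 500L, 100L, 500L))
count_string(flatten_units(gene))
```

3. **Cassette detection.** A trio (5' flank, cassette, 3' flank) is
   reported when at least one isoform chain contains the three exons
   consecutively and exactly, and at least one other isoform joins the
   two flanks by a direct junction.  For two isoforms this is equivalent
   to matching the `[2-0-1-0-2]` pattern; the chain-evidence formulation
   is the generalization we chose for three or more isoforms, where
   count strings alone cannot tell *which* isoform skips via a direct
   junction.  It also encodes the junction-evidence requirement: an
   exclusion form must actually splice flank to flank, not merely lack
   coverage.  Flank coordinates must match exactly on both boundaries —
   trios differing in a flank splice site are distinct events — and a
   cassette must be an internal exon of the including chain, so terminal
   exons can serve as flanks but never as the cassette.

```{r detect}
detect_cassette_events(gene) |> as.data.frame()
```

4. **Serialization.** Events are written as GFF3 with a `gene` record
   per event and exactly two `mRNA` children — the canonical inclusion
   (3 exons) and exclusion (2 exons) forms — regardless of how many
   source isoforms supported each form; the supporting transcript ids
   travel in an `isoforms=` attribute.  This mirrors the two-isoform
   event model of the downstream quantifier.  The event id
   `chrom:f5s-f5e@cs-ce@f3s-f3e:strand` (1-based inclusive, transcription
   order) is unique per trio and human-readable.

## Evaluation protocol

`compute_metrics()` compares a data-derived event set with a known
library under the most conservative rule: an event pair matches only if
chromosome, strand and all three exon intervals are identical.  The
*rate of known events* (RKE) is the matched fraction of data-derived
events; *recall* is the matched fraction of the known library.  Empty
denominators yield `NA` with a warning, never 0, so a vacuous comparison
cannot masquerade as a perfect one.  Strand participates in identity
even though loci alone would often suffice, because identical loci on
opposite strands describe different transcription-order events.

Known libraries aim at completeness across tissues, so raw recall
against them is expected to be low for any single dataset.  The adjusted
protocol first restricts the known set to events with adequate read
support — at least 10 reads supporting inclusion and at least 1
supporting exclusion, both thresholds inclusive and configurable — via
`filter_by_read_support()`.  Support counts arrive as a side table
(`event_id`, `inclusion_reads`, `exclusion_reads`); computing them from
alignments is a quantifier's job and out of scope here.

## Coordinate conventions

Internally every interval is 0-based half-open.  GTF and GFF3 (1-based
inclusive) are converted at the file boundary; BED12 needs no shift.
Genome-browser-style loci quoted in documentation are 1-based inclusive.
Abutting exon blocks (zero-length introns) are merged on input, since
segmentation assumes real introns; overlapping exons within one
transcript are rejected as malformed.  Strandless BED12 records are
rejected rather than guessed.

## The synthetic generator

`generate_annotation()` emulates what the detector actually consumes —
multi-isoform gene models — rather than reads or coverage.  Genes are
laid out without overlap on synthetic chromosomes (`synth1`, ...), 10
genes per chromosome, 10 kb apart.  Defaults: 50 genes, cassette
fraction 0.4, 2–3 isoforms per gene, 3–8 exons per isoform, exon
lengths 50–300 bp, intron lengths 200–5000 bp, both strands equally
likely — typical magnitudes for mammalian internal exons and compact
introns, chosen once as the package's reference conditions.  A cassette
gene carries one inclusion and one skipping isoform (plus optional exact
copies); decoy genes exercise the rules that must *not* fire: single
isoforms, identical chains, alternative first/last exon boundaries, and
a skipped form whose flank boundary is shifted (which must not match the
exact-flank rule).  The generator records the planted truth by
construction, so `simulate → find → evaluate` must return RKE = recall =
1 on noise-free configurations — and the test suite asserts exactly that
across 50 seeds.

What passing these tests shows is that the structural algorithm is
exact on its own terms; what they cannot show is robustness to
reconstruction noise in real assemblies (fragmented transcripts, missed
junctions, spurious isoforms), which enters upstream of this package.
In particular, an inclusion isoform that the assembler failed to
reconstruct makes the event undetectable here even when reads cover the
cassette exon.

## Numerical and design notes

* Determinism everywhere: groups are ordered by span, events by
  chromosome/trio start/event id, and the generator is byte-identical
  given a seed (`withr::with_seed`).  Outputs are diff-able.
* Duplicate identical transcripts add no evidence; the including and
  skipping sets simply record every isoform carrying the respective
  chain, so redundant assembler output inflates sets, never events.
* When the same trio is found in two overlapping gene groups, the event
  is emitted once with the isoform sets unioned.
* Writers are atomic (write-to-temp, rename), so a failing run never
  leaves a partial annotation behind.
* The read-support helper draws Poisson counts (defaults: mean 15
  inclusion, 2 exclusion) purely to exercise the filter; it models no
  biology.
* Problem sizes in the tests (hundreds of random gene groups of up to 6
  isoforms and 8 exons; 50-seed recovery runs of 10–12 genes) were
  chosen to exhaust the combinatorics the brute-force oracles can check
  exactly.

## Limitations

Only cassette exons are detected.  The unit/count-string machinery would
extend to retained introns and alternative donors/acceptors, but those
patterns are not defined here and are out of scope.  PSI estimation,
differential-splicing testing and plotting of read evidence belong to
the downstream quantifier.  The GFF3 reader tolerates foreign records in
third-party libraries by skipping anything that is not a
{3-exon, 2-exon} gene hierarchy, reporting the skip count; it makes no
attempt to understand other dialects.
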