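#' Pool junction support across samples
#'
#' Junction-level support filters are defined on the best single sample, so
#' pooling keeps, for every junction observed anywhere in the cohort, its
#' maximum per-sample uniquely-mapping read count.
#'
#' Junctions are identified by (chrom, start, end). When the same junction is
#' reported with conflicting defined strands across samples it is kept with
#' strand `"*"` and a warning; a defined strand otherwise wins over unknown.
#'
#' @param junction_counts Long tibble of junction counts with columns
#'   `sample_id`, `chrom`, `start`, `end`, `strand`, `count` (rows from one or
#'   more [read_sj_table()] calls).
#' @return Tibble with columns `chrom`, `start`, `end`, `strand`,
#'   `max_count`.
#' @export
pool_junction_support <- function(junction_counts) {
  stopifnot(nrow(junction_counts) >= 0)
  pooled <- junction_counts |>
    dplyr::group_by(.data$chrom, .data$start, .data$end) |>
    dplyr::summarise(
      max_count = max(.data$count),
      strand = consolidate_strand(.data$strand),
      .groups = "drop"
    ) |>
    dplyr::select("chrom", "start", "end", "strand", "max_count")
  pooled
}

consolidate_strand <- function(strands) {
  defined <- unique(strands[strands != "*"])
  if (length(defined) == 1L) return(defined)
  if (length(defined) > 1L) {
    warning("junction observed on both strands; keeping strand '*'")
    return("*")
  }
  "*"
}

#' Drop weakly supported junctions
#'
#' Requires each junction to reach a minimum read count in at least one
#' sample (default 5) before it can take part in event discovery.
#'
#' @param pooled Output of [pool_junction_support()].
#' @param min_reads Minimum pooled per-sample maximum (default 5).
#' @return The pooled tibble restricted to junctions with
#'   `max_count >= min_reads`.
#' @export
filter_min_support <- function(pooled, min_reads = 5) {
  if (min_reads < 1) stop("min_reads must be >= 1")
  pooled[pooled$max_count >= min_reads, ]
}

#' Enumerate cassette-exon junction triplets
#'
#' A skipping event is three junctions on one chromosome with compatible
#' strands: an upstream inclusion junction UJ, a downstream inclusion
#' junction DJ, and a skipping junction SJ sharing UJ's outer boundary
#' (`SJ.start == UJ.start`) and DJ's (`SJ.end == DJ.end`), with
#' non-overlapping inner introns (`UJ.end < DJ.start`) and at least one
#' exonic base between them. An exon with several alternative neighbors
#' yields one event per triplet. The result is deterministic and independent
#' of input row order.
#'
#' @param junctions Tibble with columns `chrom`, `start`, `end`, `strand`
#'   (typically the output of [filter_min_support()]).
#' @return Event tibble: `event_id`, `chrom`, `strand`, `uj_start`, `uj_end`,
#'   `dj_start`, `dj_end`, `sj_start`, `sj_end`, `exon_start`, `exon_end`,
#'   `exon_length`. Strand mixes of `+` and `-` are incompatible; `"*"` is
#'   compatible with anything and the event inherits the defined strand when
#'   one exists.
#' @export
enumerate_triplets <- function(junctions) {
  j <- tibble::as_tibble(junctions)[c("chrom", "start", "end", "strand")]
  j <- dplyr::distinct(j)
  empty <- tibble::tibble(
    event_id = character(), chrom = character(), strand = character(),
    uj_start = integer(), uj_end = integer(),
    dj_start = integer(), dj_end = integer(),
    sj_start = integer(), sj_end = integer(),
    exon_start = integer(), exon_end = integer(), exon_length = integer()
  )
  if (nrow(j) < 3) return(empty)

  sj <- dplyr::transmute(j, chrom = .data$chrom, sj_start = .data$start,
                         sj_end = .data$end, sj_strand = .data$strand)
  uj <- dplyr::transmute(j, chrom = .data$chrom, uj_start = .data$start,
                         uj_end = .data$end, uj_strand = .data$strand,
                         .key_start = .data$start)
  dj <- dplyr::transmute(j, chrom = .data$chrom, dj_start = .data$start,
                         dj_end = .data$end, dj_strand = .data$strand,
                         .key_end = .data$end)

  cand <- dplyr::inner_join(sj, uj,
                            by = c("chrom", "sj_start" = ".key_start"),
                            relationship = "many-to-many")
  cand <- dplyr::inner_join(cand, dj,
                            by = c("chrom", "sj_end" = ".key_end"),
                            relationship = "many-to-many")
  cand <- dplyr::filter(cand,
                        .data$uj_end < .data$dj_start - 1L,
                        strand_compatible3(.data$uj_strand, .data$dj_strand,
                                           .data$sj_strand))
  if (nrow(cand) == 0) return(empty)

  out <- dplyr::transmute(
    cand,
    event_id = sprintf("%s:%d-%d|%d-%d", .data$chrom, .data$uj_start,
                       .data$uj_end, .data$dj_start, .data$dj_end),
    chrom = .data$chrom,
    strand = event_strand3(.data$uj_strand, .data$dj_strand, .data$sj_strand),
    uj_start = .data$uj_start, uj_end = .data$uj_end,
    dj_start = .data$dj_start, dj_end = .data$dj_end,
    sj_start = .data$uj_start, sj_end = .data$dj_end,
    exon_start = .data$uj_end + 1L, exon_end = .data$dj_start - 1L,
    exon_length = .data$dj_start - .data$uj_end - 1L
  )
  dplyr::arrange(out, .data$chrom, .data$uj_start, .data$uj_end,
                 .data$dj_start, .data$dj_end)
}

strand_compatible3 <- function(a, b, c) {
  plus <- (a == "+") | (b == "+") | (c == "+")
  minus <- (a == "-") | (b == "-") | (c == "-")
  !(plus & minus)
}

event_strand3 <- function(a, b, c) {
  out <- rep("*", length(a))
  out[a == "+" | b == "+" | c == "+"] <- "+"
  out[a == "-" | b == "-" | c == "-"] <- "-"
  out
}

#' Inner-junction balance filter
#'
#' Keeps an event only if, in every sample of the dataset, the upstream and
#' downstream inclusion-junction counts are similar:
#' `|UJC - DJC| < max_abs_diff` or
#' `|UJC - DJC| < ratio_mult * min(UJC, DJC)` (both inequalities strict).
#' A junction absent from a sample counts as 0, so a sample with `UJC = 0`
#' and `DJC >= max_abs_diff` removes the event.
#'
#' @param events Event tibble from [enumerate_triplets()].
#' @param junction_counts Long junction-count tibble covering the dataset's
#'   samples.
#' @param samples Sample ids defining "the dataset"; defaults to every
#'   sample id appearing in `junction_counts`.
#' @param max_abs_diff Absolute-difference bound (default 10).
#' @param ratio_mult Multiplier on the smaller count (default 2).
#' @return Logical vector along `events`: `TRUE` = keep.
#' @export
balance_filter <- function(events, junction_counts, samples = NULL,
                           max_abs_diff = 10, ratio_mult = 2) {
  if (nrow(events) == 0) return(logical(0))
  if (is.null(samples)) samples <- unique(junction_counts$sample_id)
  uj_key <- paste(events$chrom, events$uj_start, events$uj_end)
  dj_key <- paste(events$chrom, events$dj_start, events$dj_end)
  cnt <- junction_count_matrix(junction_counts, unique(c(uj_key, dj_key)),
                               samples)
  ujc <- cnt[uj_key, , drop = FALSE]
  djc <- cnt[dj_key, , drop = FALSE]
  d <- abs(ujc - djc)
  ok <- (d < max_abs_diff) | (d < ratio_mult * pmin(ujc, djc))
  unname(rowSums(!ok) == 0)
}

# counts matrix (junction key x sample), zeros where unobserved
junction_count_matrix <- function(junction_counts, keys, samples) {
  m <- matrix(0, nrow = length(keys), ncol = length(samples),
              dimnames = list(keys, samples))
  jc <- junction_counts[junction_counts$sample_id %in% samples, ]
  k <- paste(jc$chrom, jc$start, jc$end)
  hit <- k %in% keys
  m[cbind(match(k[hit], keys), match(jc$sample_id[hit], samples))] <-
    jc$count[hit]
  m
}

#' Discover cassette-exon skipping events in one dataset
#'
#' Convenience wrapper chaining [pool_junction_support()],
#' [filter_min_support()], [enumerate_triplets()] and [balance_filter()] over
#' the samples of one dataset (typically one cancer-type cohort).
#'
#' @inheritParams balance_filter
#' @inheritParams filter_min_support
#' @param junction_counts Long junction-count tibble.
#' @return Event tibble of surviving skipping events; attribute `funnel`
#'   records the junction/event counts after each filter.
#' @export
discover_events <- function(junction_counts, samples = NULL, min_reads = 5,
                            max_abs_diff = 10, ratio_mult = 2) {
  if (is.null(samples)) samples <- unique(junction_counts$sample_id)
  jc <- junction_counts[junction_counts$sample_id %in% samples, ]
  pooled <- pool_junction_support(jc)
  supported <- filter_min_support(pooled, min_reads)
  events <- enumerate_triplets(supported)
  keep <- balance_filter(events, jc, samples, max_abs_diff, ratio_mult)
  out <- events[keep, ]
  attr(out, "funnel") <- c(
    junctions_observed = nrow(pooled),
    junctions_supported = nrow(supported),
    triplets_enumerated = nrow(events),
    events_balanced = nrow(out)
  )
  out
}
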