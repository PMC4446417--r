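#' Classify cross-cancer recurrence and coherence of differential events
#'
#' Events significantly altered in several cancer types are "coherent" when
#' the mean PSI change has the same sign in every type where the event is
#' significant, and "non-coherent" otherwise; events significant in a single
#' type are labeled "single". The identity of the discordant (minority-sign)
#' types is reported so downstream summaries can, e.g., single out one
#' outlier cancer type.
#'
#' @param calls Differential-call tibble from [call_differential()], covering
#'   one or more cancer types.
#' @return Tibble with one row per event significant anywhere: `event_id`,
#'   `n_types`, `coherence` (`single` / `coherent` / `non_coherent`),
#'   `discordant_types` (comma-separated minority-sign types, `""` if none)
#'   and `delta_by_type` (list-column of named signed mean dPSI).
#' @export
classify_recurrence <- function(calls) {
  sig <- calls[calls$significant, ]
  if (nrow(sig) == 0) {
    return(tibble::tibble(event_id = character(), n_types = integer(),
                          coherence = character(),
                          discordant_types = character(),
                          delta_by_type = list()))
  }
  sig |>
    dplyr::group_by(.data$event_id) |>
    dplyr::summarise(
      n_types = dplyr::n(),
      coherence = coherence_label(.data$mean_delta_psi),
      discordant_types = discordant_label(.data$cancer_type,
                                          .data$mean_delta_psi),
      delta_by_type = list(stats::setNames(.data$mean_delta_psi,
                                           .data$cancer_type)),
      .groups = "drop"
    )
}

coherence_label <- function(deltas) {
  if (length(deltas) == 1L) return("single")
  s <- sign(deltas)
  if (all(s == s[1L])) "coherent" else "non_coherent"
}

discordant_label <- function(types, deltas) {
  if (length(deltas) < 2L) return("")
  s <- sign(deltas)
  if (all(s == s[1L])) return("")
  # minority-sign types; a 2-type tie reports the exclusion side
  minority <- if (sum(s > 0) < sum(s < 0)) 1 else -1
  paste(sort(types[s == minority]), collapse = ",")
}

#' Recurrence table in wide form
#'
#' The data behind a cross-cancer heatmap: one row per recurrent event, one
#' signed mean dPSI column per cancer type (NA where not significant), plus
#' the coherence label.
#'
#' @inheritParams classify_recurrence
#' @return Wide tibble: `event_id`, one column per cancer type, `n_types`,
#'   `coherence`.
#' @export
recurrence_table <- function(calls) {
  rec <- classify_recurrence(calls)
  sig <- calls[calls$significant, c("event_id", "cancer_type", "mean_delta_psi")]
  wide <- tidyr::pivot_wider(sig, names_from = "cancer_type",
                             values_from = "mean_delta_psi")
  dplyr::left_join(wide, rec[c("event_id", "n_types", "coherence")],
                   by = "event_id")
}

#' Detect candidate splicing markers
#'
#' A marker is an event whose PSI changes consistently — same direction,
#' `|dPSI| >= delta` — in at least a fraction `frac` of the examined matched
#' pairs of one cancer type. Pairs qualify in the inclusion direction when
#' `dPSI >= delta` and in the exclusion direction when `dPSI <= -delta`;
#' `fraction_changed` is the larger direction's count over the pairs
#' examined.
#'
#' @param psi A `psi_matrix`.
#' @param manifest Sample manifest.
#' @param cancer_type Single cancer type to examine.
#' @param delta Per-pair |dPSI| threshold (default 0.10).
#' @param frac Required fraction of pairs (default 0.90).
#' @param min_cov,min_pairs High-expression filter parameters.
#' @return Tibble: `event_id`, `cancer_type`, `n_pairs_examined`, `n_up`,
#'   `n_down`, `fraction_changed`, `mean_delta_psi`, `marker`.
#' @export
detect_markers <- function(psi, manifest, cancer_type, delta = 0.10,
                           frac = 0.90, min_cov = 10, min_pairs = 15) {
  keep <- high_expression_filter(psi, manifest, cancer_type,
                                 min_cov, min_pairs)
  empty <- tibble::tibble(
    event_id = character(), cancer_type = character(),
    n_pairs_examined = integer(), n_up = integer(), n_down = integer(),
    fraction_changed = double(), mean_delta_psi = double(), marker = logical()
  )
  if (length(keep) == 0) return(empty)
  pairs <- matched_pairs(manifest, cancer_type)
  pairs <- pairs[pairs$tumor_sample %in% colnames(psi$psi) &
                   pairs$normal_sample %in% colnames(psi$psi), ]
  usable <- psi$coverage[keep, pairs$tumor_sample, drop = FALSE] >= min_cov &
    psi$coverage[keep, pairs$normal_sample, drop = FALSE] >= min_cov
  d <- psi$psi[keep, pairs$tumor_sample, drop = FALSE] -
    psi$psi[keep, pairs$normal_sample, drop = FALSE]
  d[!usable] <- NA_real_
  n_used <- unname(rowSums(usable))
  n_up <- unname(rowSums(d >= delta, na.rm = TRUE))
  n_down <- unname(rowSums(d <= -delta, na.rm = TRUE))
  fraction <- pmax(n_up, n_down) / n_used
  tibble::tibble(
    event_id = keep,
    cancer_type = cancer_type,
    n_pairs_examined = as.integer(n_used),
    n_up = as.integer(n_up),
    n_down = as.integer(n_down),
    fraction_changed = fraction,
    mean_delta_psi = unname(rowMeans(d, na.rm = TRUE)),
    marker = fraction >= frac
  )
}

#' Reading-frame preservation of a cassette event
#'
#' Inclusion or exclusion of the cassette leaves the reading frame intact iff
#' the total exonic length is a multiple of 3. Events spanning several
#' consecutive exons pass their lengths as a vector, which is summed.
#'
#' @param exon_length A numeric vector of per-event exon lengths, or a list
#'   whose elements are the exon lengths of multi-exon events (summed per
#'   element).
#' @return Logical vector: `TRUE` where the total length is divisible by 3.
#' @export
frame_preserved <- function(exon_length) {
  if (is.list(exon_length)) {
    exon_length <- vapply(exon_length, sum, numeric(1))
  }
  exon_length %% 3 == 0
}

#' Chi-square test of two proportions
#'
#' 2x2 chi-square test without continuity correction comparing `k1 / n1`
#' against `k2 / n2` (e.g. frame-preservation rates in altered versus
#' background exons).
#'
#' @param k1,n1 Successes and total in group 1.
#' @param k2,n2 Successes and total in group 2.
#' @return List with `statistic` and `p_value`.
#' @export
proportion_test <- function(k1, n1, k2, n2) {
  stopifnot(k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2, n1 > 0, n2 > 0)
  m <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected == 0)) {
    stop("a 2x2 expected cell is zero; use an exact test instead")
  }
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(res$statistic), p_value = unname(res$p.value))
}

#' Upper-tail hypergeometric overlap test
#'
#' Probability of observing at least the given overlap between two sets
#' drawn from a common universe: `P[X >= |A intersect B|]` with
#' `X ~ Hypergeometric(|universe|, |B|, |A|)`.
#'
#' @param set_a,set_b Id vectors, both subsets of `universe`.
#' @param universe Id vector of the population.
#' @return List with `overlap`, `n_a`, `n_b`, `n_universe`, `p_value`.
#' @export
hypergeom_overlap <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop("both sets must be subsets of the universe")
  }
  k <- length(intersect(set_a, set_b))
  p <- stats::phyper(k - 1, length(set_b), length(universe) - length(set_b),
                     length(set_a), lower.tail = FALSE)
  list(overlap = k, n_a = length(set_a), n_b = length(set_b),
       n_universe = length(universe), p_value = p)
}

#' Events overlapping an annotation interval set
#'
#' Reports the events whose cassette exon overlaps any annotation interval
#' on the same chromosome by at least one base and, when `min_frac > 0`, by
#' at least that fraction of the exon length.
#'
#' @param events Event tibble (`chrom`, `exon_start`, `exon_end`,
#'   `event_id`; 1-based inclusive).
#' @param annotation Interval tibble (`chrom`, `start`, `end`; 1-based
#'   inclusive, e.g. from [read_bed()]).
#' @param min_frac Minimum overlapped fraction of the exon (default 0 = any
#'   overlap).
#' @return Character vector of overlapping event ids.
#' @export
interval_overlap <- function(events, annotation, min_frac = 0) {
  if (nrow(events) == 0 || nrow(annotation) == 0) return(character(0))
  hits <- character(0)
  for (ch in intersect(unique(events$chrom), unique(annotation$chrom))) {
    ev <- events[events$chrom == ch, ]
    an <- annotation[annotation$chrom == ch, ]
    ir_ev <- IRanges::IRanges(ev$exon_start, ev$exon_end)
    ir_an <- IRanges::IRanges(an$start, an$end)
    ov <- IRanges::findOverlaps(ir_ev, ir_an)
    if (length(ov) == 0) next
    qi <- S4Vectors::queryHits(ov)
    w <- IRanges::width(IRanges::pintersect(ir_ev[qi],
                                            ir_an[S4Vectors::subjectHits(ov)]))
    frac <- w / IRanges::width(ir_ev[qi])
    hits <- c(hits, ev$event_id[unique(qi[frac >= min_frac & w >= 1])])
  }
  unique(hits)
}

#' Correlation between an event's PSI and its gene's expression
#'
#' Pearson correlation over samples with both values present; used to check
#' whether a PSI change merely tracks gene expression. Correlations with
#' `|r| < 0.3` are flagged weak.
#'
#' @param psi_row PSI values over samples.
#' @param expr_row Normalized expression values over the same samples.
#' @return List with `r`, `n` and `weak` (`|r| < 0.3`); `r` is `NA` with a
#'   warning when either vector is constant or fewer than 3 complete pairs
#'   exist.
#' @export
psi_expression_correlation <- function(psi_row, expr_row) {
  stopifnot(length(psi_row) == length(expr_row))
  ok <- !is.na(psi_row) & !is.na(expr_row)
  x <- psi_row[ok]; y <- expr_row[ok]
  if (length(x) < 3) {
    warning("fewer than 3 complete sample pairs; correlation undefined")
    return(list(r = NA_real_, n = length(x), weak = NA))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(list(r = NA_real_, n = length(x), weak = NA))
  }
  r <- stats::cor(x, y, method = "pearson")
  list(r = r, n = length(x), weak = abs(r) < 0.3)
}

#' Correlation between two dPSI profiles
#'
#' Pearson correlation over shared events between two event -> dPSI
#' mappings, e.g. a cancer type's mean tumor-normal dPSI against a
#' splicing-factor knockdown's dPSI, or two samples' PSI profiles for QC.
#'
#' @param delta_a,delta_b Named numeric vectors (names = event ids).
#' @return List with `r`, `p_value`, `n` (shared events); all `NA` when
#'   fewer than 3 events are shared.
#' @export
delta_psi_correlation <- function(delta_a, delta_b) {
  shared <- intersect(names(delta_a), names(delta_b))
  shared <- shared[!is.na(delta_a[shared]) & !is.na(delta_b[shared])]
  if (length(shared) < 3) {
    return(list(r = NA_real_, p_value = NA_real_, n = length(shared)))
  }
  ct <- stats::cor.test(delta_a[shared], delta_b[shared], method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(shared))
}
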