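#' Percent spliced-in from junction read counts
#'
#' PSI estimates the fraction of transcripts including the cassette exon:
#' `PSI = 0.5 (UJC + DJC) / (0.5 (UJC + DJC) + SJC)`, the inclusion evidence
#' (average of the two inner junction counts) over total evidence. Undefined
#' (NA) when all three counts are zero.
#'
#' @param ujc,djc,sjc Non-negative read counts for the upstream, downstream
#'   and skipping junctions (vectorized).
#' @return Numeric vector of PSI values in `[0, 1]`, `NA` where the
#'   denominator is zero.
#' @export
compute_psi <- function(ujc, djc, sjc) {
  if (any(c(ujc, djc, sjc) < 0, na.rm = TRUE)) {
    stop("junction counts must be non-negative")
  }
  incl <- 0.5 * (ujc + djc)
  denom <- incl + sjc
  ifelse(denom > 0, incl / denom, NA_real_)
}

#' Event coverage from junction read counts
#'
#' Total junction evidence for one event in one sample,
#' `0.5 (UJC + DJC) + SJC`; the quantity thresholded by the
#' high-expression filter.
#'
#' @inheritParams compute_psi
#' @return Numeric vector of coverages.
#' @export
junction_coverage <- function(ujc, djc, sjc) {
  if (any(c(ujc, djc, sjc) < 0, na.rm = TRUE)) {
    stop("junction counts must be non-negative")
  }
  0.5 * (ujc + djc) + sjc
}

#' Build the events-by-samples PSI matrix
#'
#' Looks up each event's three junction counts in every sample and computes
#' PSI and coverage. PSI is `NA` exactly where coverage is 0.
#'
#' @param events Event tibble from [enumerate_triplets()] /
#'   [discover_events()].
#' @param junction_counts Long junction-count tibble.
#' @param samples Sample ids to include as columns (default: all in
#'   `junction_counts`).
#' @return A `psi_matrix` object: list with `psi` and `coverage` matrices
#'   (rows = event ids, columns = sample ids) and the `events` tibble.
#' @export
build_psi_matrix <- function(events, junction_counts, samples = NULL) {
  if (is.null(samples)) samples <- unique(junction_counts$sample_id)
  uj_key <- paste(events$chrom, events$uj_start, events$uj_end)
  dj_key <- paste(events$chrom, events$dj_start, events$dj_end)
  sj_key <- paste(events$chrom, events$sj_start, events$sj_end)
  cnt <- junction_count_matrix(junction_counts,
                               unique(c(uj_key, dj_key, sj_key)), samples)
  ujc <- cnt[uj_key, , drop = FALSE]
  djc <- cnt[dj_key, , drop = FALSE]
  sjc <- cnt[sj_key, , drop = FALSE]
  incl <- 0.5 * (ujc + djc)
  cov <- incl + sjc
  psi <- incl / cov
  psi[cov == 0] <- NA_real_
  dimnames(psi) <- dimnames(cov) <- list(events$event_id, samples)
  structure(list(psi = psi, coverage = cov, events = events),
            class = "psi_matrix")
}

#' @export
print.psi_matrix <- function(x, ...) {
  cat("<psi_matrix> ", nrow(x$psi), " events x ", ncol(x$psi), " samples; ",
      sum(is.na(x$psi)), " missing cells\n", sep = "")
  invisible(x)
}

#' Write / read a PSI matrix as TSV
#'
#' Events as rows, samples as columns, `NA` for missing cells. Coverage is
#' written alongside with suffix `.coverage.tsv` so the pair round-trips.
#'
#' @param psi A `psi_matrix`.
#' @param path Output TSV path.
#' @export
write_psi_matrix <- function(psi, path) {
  df <- data.frame(event_id = rownames(psi$psi), psi$psi,
                   check.names = FALSE)
  readr::write_tsv(tibble::as_tibble(df), path, na = "NA")
  cov_path <- sub("\\.tsv$", ".coverage.tsv", path)
  dfc <- data.frame(event_id = rownames(psi$coverage), psi$coverage,
                    check.names = FALSE)
  readr::write_tsv(tibble::as_tibble(dfc), cov_path, na = "NA")
  invisible(path)
}

#' High-expression event filter
#'
#' Keeps events whose three junctions carry enough reads — coverage
#' `0.5 (UJC + DJC) + SJC >= min_cov` — in both members of at least
#' `min_pairs` matched tumor/normal pairs of the cancer type.
#'
#' @param psi A `psi_matrix`.
#' @param manifest Sample manifest.
#' @param cancer_type Optional cancer type restriction for the pairs.
#' @param min_cov Minimum per-sample coverage (default 10).
#' @param min_pairs Minimum number of fully covered pairs (default 15).
#' @return Character vector of surviving event ids.
#' @export
high_expression_filter <- function(psi, manifest, cancer_type = NULL,
                                   min_cov = 10, min_pairs = 15) {
  if (min_pairs < 1) stop("min_pairs must be >= 1")
  pairs <- matched_pairs(manifest, cancer_type)
  pairs <- pairs[pairs$tumor_sample %in% colnames(psi$coverage) &
                   pairs$normal_sample %in% colnames(psi$coverage), ]
  if (nrow(pairs) == 0) return(character(0))
  covT <- psi$coverage[, pairs$tumor_sample, drop = FALSE]
  covN <- psi$coverage[, pairs$normal_sample, drop = FALSE]
  n_ok <- rowSums(covT >= min_cov & covN >= min_cov)
  rownames(psi$coverage)[n_ok >= min_pairs]
}

#' Paired Wilcoxon signed-rank test on PSI values
#'
#' Two-sided test of a PSI shift between matched tumor and normal samples.
#' Zero differences are dropped before ranking. The exact null distribution
#' is used when the number of nonzero differences is at most 25 and their
#' absolute values are untied; otherwise the normal approximation with tie
#' and continuity correction applies. All-zero differences give p = 1;
#' fewer than 2 usable pairs give `NA` (untestable).
#'
#' @param tumor,normal Equal-length paired PSI vectors; pairs with any `NA`
#'   are removed.
#' @return Two-sided p-value, or `NA_real_` when untestable.
#' @export
paired_wilcoxon <- function(tumor, normal) {
  stopifnot(length(tumor) == length(normal))
  ok <- !is.na(tumor) & !is.na(normal)
  d <- tumor[ok] - normal[ok]
  if (length(d) < 2) return(NA_real_)
  dnz <- d[d != 0]
  if (length(dnz) == 0) return(1)
  exact <- length(dnz) <= 25 && !any(duplicated(abs(dnz)))
  res <- suppressWarnings(
    stats::wilcox.test(dnz, mu = 0, exact = exact, correct = TRUE)
  )
  unname(res$p.value)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p Vector of p-values in `[0, 1]`; `NA` entries are passed through
#'   and do not count toward the number of tests.
#' @return Vector of q-values: monotone step-up adjustment, capped at 1,
#'   elementwise `>= p`.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Call differential splicing between matched tumor/normal pairs
#'
#' For each highly expressed event of a cancer type, computes the mean paired
#' PSI difference (tumor minus normal) and a paired Wilcoxon p-value over the
#' usable pairs — pairs in which both samples reach `min_cov` coverage —
#' then adjusts p-values by Benjamini-Hochberg across the events of that
#' cancer type. An event is significant iff `q <= fdr` and
#' `|mean dPSI| >= min_delta`.
#'
#' @param psi A `psi_matrix` covering the samples of the manifest.
#' @param manifest Sample manifest.
#' @param cancer_type Cancer type(s) to test; default all in the manifest.
#' @param fdr FDR threshold (default 0.05).
#' @param min_delta Minimum |mean dPSI| (default 0.10).
#' @param min_cov,min_pairs Coverage filter parameters, see
#'   [high_expression_filter()].
#' @return Tibble of differential calls: `event_id`, `cancer_type`,
#'   `n_pairs`, `mean_delta_psi`, `p_value`, `q_value`, `direction`
#'   (`inclusion` iff mean dPSI > 0), `significant`.
#' @export
call_differential <- function(psi, manifest, cancer_type = NULL,
                              fdr = 0.05, min_delta = 0.10,
                              min_cov = 10, min_pairs = 15) {
  manifest <- validate_manifest(manifest)
  if (is.null(cancer_type)) cancer_type <- unique(manifest$cancer_type)
  out <- lapply(cancer_type, function(ct) {
    call_differential_one(psi, manifest, ct, fdr, min_delta,
                          min_cov, min_pairs)
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) warning("no testable events in any cancer type")
  res
}

call_differential_one <- function(psi, manifest, ct, fdr, min_delta,
                                  min_cov, min_pairs) {
  empty <- tibble::tibble(
    event_id = character(), cancer_type = character(), n_pairs = integer(),
    mean_delta_psi = double(), p_value = double(), q_value = double(),
    direction = character(), significant = logical()
  )
  keep <- high_expression_filter(psi, manifest, ct, min_cov, min_pairs)
  if (length(keep) == 0) return(empty)
  pairs <- matched_pairs(manifest, ct)
  pairs <- pairs[pairs$tumor_sample %in% colnames(psi$psi) &
                   pairs$normal_sample %in% colnames(psi$psi), ]
  psiT <- psi$psi[keep, pairs$tumor_sample, drop = FALSE]
  psiN <- psi$psi[keep, pairs$normal_sample, drop = FALSE]
  usable <- psi$coverage[keep, pairs$tumor_sample, drop = FALSE] >= min_cov &
    psi$coverage[keep, pairs$normal_sample, drop = FALSE] >= min_cov
  delta <- psiT - psiN
  delta[!usable] <- NA_real_
  n_used <- unname(rowSums(usable))
  mean_delta <- unname(rowMeans(delta, na.rm = TRUE))
  p <- vapply(seq_len(nrow(delta)), function(i) {
    paired_wilcoxon(psiT[i, usable[i, ]], psiN[i, usable[i, ]])
  }, numeric(1))
  q <- bh_fdr(p)
  tibble::tibble(
    event_id = keep,
    cancer_type = ct,
    n_pairs = as.integer(n_used),
    mean_delta_psi = mean_delta,
    p_value = p,
    q_value = q,
    direction = ifelse(mean_delta > 0, "inclusion", "exclusion"),
    significant = !is.na(q) & q <= fdr & abs(mean_delta) >= min_delta
  )
}
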