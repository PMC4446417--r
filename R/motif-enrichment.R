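#' Extract exon and flanking-intron windows of skipping events
#'
#' For each stranded event, returns three windows in transcription
#' orientation: the cassette exon body, the `flank` intronic bases of the
#' upstream intron adjacent to the exon, and the `flank` intronic bases of
#' the downstream intron adjacent to the exon. Introns shorter than `flank`
#' contribute their full length; windows never cross into neighboring exons.
#' On the `-` strand the genomic roles of the two introns swap and every
#' sequence is reverse-complemented, so "upstream" is always upstream in the
#' direction of transcription. Events of unknown strand are skipped with a
#' message (motif windows are direction-specific).
#'
#' @param events Event tibble.
#' @param genome Named [Biostrings::DNAStringSet] or named character vector.
#' @param flank Flanking-intron window size in nt (default 250).
#' @return Tibble: `event_id`, `region` (`exon`, `upstream_intron`,
#'   `downstream_intron`), `chrom`, `start`, `end` (genomic, 1-based
#'   inclusive), `strand`, `seq` (transcription orientation).
#' @export
extract_regions <- function(events, genome, flank = 250) {
  ev <- tibble::as_tibble(events)
  skipped <- ev$strand == "*"
  if (any(skipped)) {
    message(sum(skipped), " event(s) of unknown strand skipped in region extraction")
    ev <- ev[!skipped, ]
  }
  if (nrow(ev) == 0) {
    return(tibble::tibble(event_id = character(), region = character(),
                          chrom = character(), start = integer(),
                          end = integer(), strand = character(),
                          seq = character()))
  }
  uj_len <- ev$uj_end - ev$uj_start + 1L
  dj_len <- ev$dj_end - ev$dj_start + 1L
  uj_win_start <- ev$uj_end - pmin(flank, uj_len) + 1L   # UJ slice next to exon
  uj_win_end <- ev$uj_end
  dj_win_start <- ev$dj_start                            # DJ slice next to exon
  dj_win_end <- ev$dj_start + pmin(flank, dj_len) - 1L
  plus <- ev$strand == "+"
  up_start <- ifelse(plus, uj_win_start, dj_win_start)
  up_end <- ifelse(plus, uj_win_end, dj_win_end)
  down_start <- ifelse(plus, dj_win_start, uj_win_start)
  down_end <- ifelse(plus, dj_win_end, uj_win_end)

  out <- tibble::tibble(
    event_id = rep(ev$event_id, 3L),
    region = rep(c("exon", "upstream_intron", "downstream_intron"),
                 each = nrow(ev)),
    chrom = rep(ev$chrom, 3L),
    start = c(ev$exon_start, up_start, down_start),
    end = c(ev$exon_end, up_end, down_end),
    strand = rep(ev$strand, 3L)
  )
  out$seq <- fetch_many(genome, out$chrom, out$start, out$end, out$strand)
  dplyr::arrange(out, .data$event_id, .data$region)
}

# vectorized sequence fetch; one as.character per chromosome
fetch_many <- function(genome, chrom, start, end, strand) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  seqs <- character(length(chrom))
  for (ch in unique(chrom)) {
    i <- chrom == ch
    if (!ch %in% names(genome)) stop("chromosome '", ch, "' not in genome")
    s <- toupper(as.character(genome[[ch]]))
    if (any(start[i] < 1) || any(end[i] > nchar(s))) {
      stop("region outside chromosome '", ch, "'")
    }
    seqs[i] <- substring(s, start[i], end[i])
  }
  neg <- strand == "-"
  if (any(neg)) seqs[neg] <- reverse_complement(seqs[neg])
  seqs
}

#' k-mers present in a sequence
#'
#' Set of all length-`k` substrings over A/C/G/T occurring at least once;
#' substrings containing any other letter (e.g. N) are dropped. Presence,
#' not multiplicity: the enrichment test's sampling unit is the exon, so a
#' k-mer is recorded once per region regardless of copy number.
#'
#' @param sequence Nucleotide string.
#' @param k k-mer length (4, 5 or 6 in the standard scan).
#' @return Character vector of distinct k-mers (empty if the sequence is
#'   shorter than `k`).
#' @export
kmer_presence <- function(sequence, k) {
  n <- nchar(sequence)
  if (n < k) return(character(0))
  subs <- substring(sequence, 1:(n - k + 1), k:n)
  unique(subs[!grepl("[^ACGT]", subs)])
}

# presence matrix (sequences x 4^k kmers) via Biostrings
kmer_presence_matrix <- function(seqs, k) {
  Biostrings::oligonucleotideFrequency(Biostrings::DNAStringSet(seqs),
                                       width = k) > 0
}

#' Direction-stratified k-mer enrichment scan
#'
#' Tests, for every k-mer present in at least one foreground region, whether
#' the fraction of foreground exons whose region contains it exceeds
#' expectation under sampling without replacement from the combined
#' foreground + background exon population (upper-tail hypergeometric).
#' Exon-body sequences are scanned with both directions pooled; the two
#' flanking-intron windows are scanned separately for exons more included
#' versus more excluded in tumors, since splicing factors act differently
#' up- and downstream of their binding sites. Benjamini-Hochberg adjustment
#' is applied across all k-mers (all k pooled) within each
#' (region, direction) stratum.
#'
#' @param foreground Region tibble ([extract_regions()]) of the altered
#'   exons, with an added `direction` column (`included` / `excluded`).
#' @param background Region tibble of the highly expressed, non-altered
#'   exons (no direction needed).
#' @param k k-mer lengths to scan (default `4:6`).
#' @param fdr Significance threshold on q (default 0.01).
#' @param cancer_type Label carried into the output (default `NA`).
#' @param motif_table Motif-to-factor mapping for annotation, see
#'   [map_motif_to_factor()].
#' @return Tibble: `kmer`, `k`, `region`, `direction`, `cancer_type`,
#'   `fg_with`, `fg_total`, `bg_with`, `bg_total`, `p_value`, `q_value`,
#'   `significant`, `factors`.
#' @export
enrichment_scan <- function(foreground, background, k = 4:6, fdr = 0.01,
                            cancer_type = NA_character_,
                            motif_table = default_motif_table()) {
  stopifnot("direction" %in% names(foreground))
  strata <- list(list(region = "exon", direction = "pooled"))
  for (reg in c("upstream_intron", "downstream_intron")) {
    for (dir in intersect(c("included", "excluded"),
                          unique(foreground$direction))) {
      strata <- c(strata, list(list(region = reg, direction = dir)))
    }
  }
  res <- lapply(strata, function(st) {
    fg <- foreground[foreground$region == st$region, ]
    if (st$direction != "pooled") fg <- fg[fg$direction == st$direction, ]
    bg <- background[background$region == st$region, ]
    if (nrow(fg) == 0 || nrow(bg) == 0) {
      warning("empty stratum skipped: ", st$region, "/", st$direction)
      return(NULL)
    }
    scan_stratum(fg, bg, k, st$region, st$direction, cancer_type)
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) return(out)
  out <- out |>
    dplyr::group_by(.data$region, .data$direction) |>
    dplyr::mutate(q_value = bh_fdr(.data$p_value)) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = .data$q_value <= fdr,
                  factors = map_motif_to_factor(.data$kmer, motif_table)) |>
    dplyr::arrange(.data$region, .data$direction, .data$p_value)
  out
}

scan_stratum <- function(fg, bg, ks, region, direction, cancer_type) {
  res <- lapply(ks, function(k) {
    pf <- kmer_presence_matrix(fg$seq, k)
    pb <- kmer_presence_matrix(bg$seq, k)
    fg_with <- colSums(pf)
    keep <- fg_with >= 1
    if (!any(keep)) return(NULL)
    kmers <- names(fg_with)[keep]
    fg_with <- unname(fg_with[keep])
    bg_with <- unname(colSums(pb)[keep])
    n_fg <- nrow(pf); n_bg <- nrow(pb)
    K <- fg_with + bg_with
    p <- stats::phyper(fg_with - 1, K, n_fg + n_bg - K, n_fg,
                       lower.tail = FALSE)
    tibble::tibble(
      kmer = kmers, k = k, region = region, direction = direction,
      cancer_type = cancer_type,
      fg_with = as.integer(fg_with), fg_total = n_fg,
      bg_with = as.integer(bg_with), bg_total = n_bg,
      p_value = p
    )
  })
  dplyr::bind_rows(res)
}

#' Default motif-to-splicing-factor table
#'
#' Consensus binding k-mers with a well-established literal form: RBFOX
#' (TGCATG / GCATG) and QKI (ACTAAC / CTAAC / ACTAA). Consensus sets for
#' other factors (PTB, CELF, MBNL, ...) vary across studies and are supplied
#' by the user via [read_motif_table()].
#'
#' @return Tibble with columns `factor` and `motif`.
#' @export
default_motif_table <- function() {
  tibble::tibble(
    factor = c("RBFOX", "RBFOX", "QKI", "QKI", "QKI"),
    motif = c("TGCATG", "GCATG", "ACTAAC", "CTAAC", "ACTAA")
  )
}

#' Read a motif-to-factor mapping
#' @param path Two-column TSV with header `factor`, `motif`.
#' @return Tibble with columns `factor`, `motif`.
#' @export
read_motif_table <- function(path) {
  readr::read_tsv(path, col_types = "cc")[c("factor", "motif")]
}

#' Map k-mers to splicing factors
#'
#' A k-mer maps to every factor whose consensus set contains it exactly, or
#' whose (shorter) consensus occurs as a substring of the k-mer.
#'
#' @param kmers Character vector of k-mers.
#' @param motif_table Mapping table, see [default_motif_table()].
#' @return Character vector parallel to `kmers`: comma-separated factor
#'   labels, `""` when unmapped.
#' @export
map_motif_to_factor <- function(kmers, motif_table = default_motif_table()) {
  vapply(kmers, function(km) {
    hit <- motif_table$motif == km |
      (nchar(motif_table$motif) < nchar(km) &
         vapply(motif_table$motif, grepl, logical(1), x = km, fixed = TRUE))
    paste(sort(unique(motif_table$factor[hit])), collapse = ",")
  }, character(1), USE.NAMES = FALSE)
}

#' Genomic occurrences of a k-mer within extracted regions
#'
#' Scans region sequences (transcription orientation) for literal matches
#' and maps each match back to genomic coordinates, accounting for strand.
#'
#' @param regions Region tibble from [extract_regions()].
#' @param kmer k-mer to locate.
#' @return Tibble: `event_id`, `region`, `chrom`, `start`, `end` (genomic,
#'   1-based inclusive), `strand`.
#' @export
find_motif_occurrences <- function(regions, kmer) {
  klen <- nchar(kmer)
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    m <- gregexpr(kmer, regions$seq[i], fixed = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    pos <- as.integer(m)
    if (regions$strand[i] == "-") {
      g_end <- regions$end[i] - pos + 1L
      g_start <- g_end - klen + 1L
    } else {
      g_start <- regions$start[i] + pos - 1L
      g_end <- g_start + klen - 1L
    }
    tibble::tibble(event_id = regions$event_id[i], region = regions$region[i],
                   chrom = regions$chrom[i], start = g_start, end = g_end,
                   strand = regions$strand[i])
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(event_id = character(), region = character(),
                          chrom = character(), start = integer(),
                          end = integer(), strand = character())
  }
  out
}

#' Mean conservation profile around motif occurrences
#'
#' Averages per-base conservation over all occurrences at each relative
#' offset from the motif midpoint (midpoint = `start + floor((len - 1) / 2)`
#' on the genomic strand; even-length motifs take the left-of-center base).
#' Foreground (altered-exon) and background occurrences are profiled
#' side by side. Track positions without data are excluded from the means.
#'
#' @param occurrences Tibble with columns `chrom`, `start`, `end` and
#'   `group` (`"foreground"` / `"background"`).
#' @param track A `cons_track`.
#' @param half_window Profile half-width in bases (default 50).
#' @return Tibble: `offset` in `[-half_window, half_window]`, `mean_fg`,
#'   `n_fg`, `mean_bg`, `n_bg` (n = occurrences with data at that offset).
#'   Empty when there are no occurrences.
#' @export
conservation_profile <- function(occurrences, track, half_window = 50) {
  if (nrow(occurrences) == 0) {
    return(tibble::tibble(offset = integer(), mean_fg = double(),
                          n_fg = integer(), mean_bg = double(),
                          n_bg = integer()))
  }
  offsets <- seq(-half_window, half_window)
  prof <- function(occ) {
    if (nrow(occ) == 0) {
      return(list(mean = rep(NA_real_, length(offsets)),
                  n = rep(0L, length(offsets))))
    }
    mid <- occ$start + floor((occ$end - occ$start) / 2)
    sums <- numeric(length(offsets))
    ns <- integer(length(offsets))
    for (i in seq_len(nrow(occ))) {
      sc <- track_score(track, occ$chrom[i], mid[i] + offsets)
      ok <- !is.na(sc)
      sums[ok] <- sums[ok] + sc[ok]
      ns <- ns + ok
    }
    list(mean = ifelse(ns > 0, sums / ns, NA_real_), n = ns)
  }
  fg <- prof(occurrences[occurrences$group == "foreground", ])
  bg <- prof(occurrences[occurrences$group == "background", ])
  tibble::tibble(offset = offsets, mean_fg = fg$mean, n_fg = fg$n,
                 mean_bg = bg$mean, n_bg = bg$n)
}
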