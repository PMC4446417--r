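#' Read a splice-junction count table (STAR SJ.out.tab dialect)
#'
#' Parses the 9-column tab-separated junction summary emitted by split-read
#' aligners: chromosome, intron start (1-based, first intronic base), intron
#' end (1-based, last intronic base), strand code (0 = unknown, 1 = `+`,
#' 2 = `-`), intron motif code, annotation flag, uniquely-mapping read count,
#' multi-mapping read count, maximum spliced-alignment overhang.
#'
#' Only the uniquely-mapping read count is used as junction evidence; the
#' multi-mapping column is parsed and carried along but never enters any
#' downstream computation.
#'
#' @param path Path to the tab-separated junction file.
#' @param sample_id Sample identifier attached to every row. Defaults to the
#'   file name without extension.
#' @return A tibble with columns `sample_id`, `chrom`, `start`, `end`,
#'   `strand` (one of `"+"`, `"-"`, `"*"`), `count` (unique reads) and
#'   `multi_count`.
#' @export
read_sj_table <- function(path, sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble::tibble(
      sample_id = character(), chrom = character(),
      start = integer(), end = integer(), strand = character(),
      count = integer(), multi_count = integer()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L)) {
    bad <- which(nf < 9L)[1L]
    stop("malformed junction line ", bad, " in '", path,
         "': expected >= 9 tab-separated columns, found ", nf[bad])
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  num <- function(i, what) {
    v <- suppressWarnings(as.integer(col(i)))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop("malformed junction line ", bad, " in '", path,
           "': non-numeric ", what)
    }
    v
  }
  start <- num(2L, "intron start")
  end <- num(3L, "intron end")
  if (any(start > end)) {
    bad <- which(start > end)[1L]
    stop("invalid junction at line ", bad, " in '", path,
         "': start ", start[bad], " > end ", end[bad])
  }
  if (any(start < 1L)) {
    bad <- which(start < 1L)[1L]
    stop("invalid junction at line ", bad, " in '", path,
         "': coordinates must be positive")
  }
  strand_code <- num(4L, "strand code")
  if (any(!strand_code %in% 0:2)) {
    bad <- which(!strand_code %in% 0:2)[1L]
    stop("invalid strand code at line ", bad, " in '", path, "'")
  }
  count <- num(7L, "unique read count")
  if (any(count < 0L)) stop("negative read count in '", path, "'")
  tbl <- tibble::tibble(
    sample_id = sample_id,
    chrom = col(1L),
    start = start,
    end = end,
    strand = c("*", "+", "-")[strand_code + 1L],
    count = count,
    multi_count = num(8L, "multi-mapping count")
  )
  dup <- duplicated(tbl[c("chrom", "start", "end")])
  if (any(dup)) {
    stop("duplicate junction at line ", which(dup)[1L], " in '", path, "'")
  }
  tbl
}

#' Write a junction count table in the SJ.out.tab dialect
#'
#' Inverse of [read_sj_table()]: motif and annotation columns are written as
#' 0, overhang as 50.
#'
#' @param tbl Tibble with columns `chrom`, `start`, `end`, `strand`, `count`
#'   and optionally `multi_count` (default 0).
#' @param path Output path.
#' @export
write_sj_table <- function(tbl, path) {
  multi <- if ("multi_count" %in% names(tbl)) tbl$multi_count else 0L
  strand_code <- match(tbl$strand, c("*", "+", "-")) - 1L
  lines <- sprintf("%s\t%d\t%d\t%d\t0\t0\t%d\t%d\t50",
                   tbl$chrom, tbl$start, tbl$end, strand_code,
                   tbl$count, multi)
  writeLines(lines, path)
  invisible(path)
}

#' Read and validate a sample manifest
#'
#' The manifest maps each RNA-seq sample to its patient, condition and cancer
#' type; matched tumor/normal pairs (same patient, same cancer type) drive
#' every paired analysis downstream.
#'
#' @param path Tab-separated file with header columns `sample_id`,
#'   `patient_id`, `condition` (`tumor` or `normal`) and `cancer_type`.
#' @return A validated manifest tibble.
#' @export
read_manifest <- function(path) {
  m <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  validate_manifest(m)
}

#' Validate a manifest data frame
#'
#' @param manifest Data frame with columns `sample_id`, `patient_id`,
#'   `condition`, `cancer_type`.
#' @return The manifest as a tibble, invisibly checked: conditions must be
#'   `tumor`/`normal`, sample ids unique, and each (patient, condition) pair
#'   unique within a cancer type.
#' @export
validate_manifest <- function(manifest) {
  needed <- c("sample_id", "patient_id", "condition", "cancer_type")
  missing_cols <- setdiff(needed, names(manifest))
  if (length(missing_cols) > 0) {
    stop("manifest is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  m <- tibble::as_tibble(manifest)[needed]
  bad <- setdiff(unique(m$condition), c("tumor", "normal"))
  if (length(bad) > 0) {
    stop("unknown condition token(s) in manifest: ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(m$sample_id)) {
    stop("duplicate sample_id in manifest: ",
         m$sample_id[duplicated(m$sample_id)][1L])
  }
  key <- paste(m$cancer_type, m$patient_id, m$condition)
  if (anyDuplicated(key)) {
    stop("duplicate (patient, condition) within a cancer type: ",
         key[duplicated(key)][1L])
  }
  m
}

#' Matched tumor/normal pairs in a manifest
#'
#' A patient contributes a matched pair within a cancer type iff both a tumor
#' and a normal sample exist for that patient in that cancer type. Patients
#' sharing an id across cancer types are paired within each type
#' independently.
#'
#' @param manifest Validated manifest tibble.
#' @param cancer_type Optional cancer type to restrict to.
#' @return Tibble with columns `cancer_type`, `patient_id`, `tumor_sample`,
#'   `normal_sample`; attribute `unmatched` lists sample ids without a
#'   partner.
#' @export
matched_pairs <- function(manifest, cancer_type = NULL) {
  m <- validate_manifest(manifest)
  if (!is.null(cancer_type)) m <- m[m$cancer_type %in% cancer_type, ]
  wide <- tidyr::pivot_wider(m, id_cols = c("cancer_type", "patient_id"),
                             names_from = "condition",
                             values_from = "sample_id")
  for (cond in c("tumor", "normal")) {
    if (!cond %in% names(wide)) wide[[cond]] <- NA_character_
  }
  pairs <- wide[!is.na(wide$tumor) & !is.na(wide$normal), ]
  pairs <- dplyr::rename(pairs, tumor_sample = "tumor", normal_sample = "normal")
  unmatched_pat <- wide[is.na(wide$tumor) | is.na(wide$normal), ]
  unmatched <- stats::na.omit(c(unmatched_pat$tumor, unmatched_pat$normal))
  attr(pairs, "unmatched") <- as.character(unmatched)
  pairs
}

#' Load a genome from FASTA
#'
#' @param path FASTA file path.
#' @return A [Biostrings::DNAStringSet] keyed by chromosome name (first
#'   whitespace-delimited token of each header).
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Fetch a genomic subsequence
#'
#' @param genome Named [Biostrings::DNAStringSet] or named character vector.
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive interval.
#' @param strand `"+"` returns the reference sequence, `"-"` its reverse
#'   complement (transcription orientation).
#' @return Uppercase character string of length `end - start + 1`.
#' @export
fetch_sequence <- function(genome, chrom, start, end, strand = "+") {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (!chrom %in% names(genome)) stop("chromosome '", chrom, "' not in genome")
  chrom_len <- Biostrings::width(genome)[match(chrom, names(genome))]
  if (start < 1 || end > chrom_len) {
    stop("interval [", start, ",", end, "] outside chromosome '", chrom,
         "' (length ", chrom_len, ")")
  }
  if (start > end) stop("start > end")
  s <- Biostrings::subseq(genome[[chrom]], start, end)
  if (identical(strand, "-")) s <- Biostrings::reverseComplement(s)
  toupper(as.character(s))
}

#' Reverse complement of a nucleotide string
#' @param seq Character vector of A/C/G/T/N sequences.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(seq) {
  unname(as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(seq))))
}

# ---- conservation tracks ----------------------------------------------------

#' Construct a per-base conservation track
#'
#' Scores live in `[0, 1]` (phastCons-style); positions without data are `NA`
#' and are always distinguished from a true score of 0.
#'
#' @param scores Named list: chromosome -> numeric vector indexed by 1-based
#'   position (`NA` = no data).
#' @return Object of class `cons_track`.
#' @export
conservation_track <- function(scores) {
  stopifnot(is.list(scores), !is.null(names(scores)))
  for (v in scores) {
    if (any(v < 0 | v > 1, na.rm = TRUE)) {
      stop("conservation scores must lie in [0, 1]")
    }
  }
  structure(list(scores = scores), class = "cons_track")
}

#' Read a bedGraph conservation track
#'
#' bedGraph intervals are 0-based half-open; they are expanded internally to
#' 1-based per-base scores.
#'
#' @param path bedGraph file (columns chrom, start, end, score; no header).
#' @return A `cons_track`.
#' @export
read_bedgraph_track <- function(path) {
  bg <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "score"),
                          colClasses = c("character", "integer", "integer", "numeric"))
  scores <- list()
  for (ch in unique(bg$chrom)) {
    rows <- bg[bg$chrom == ch, ]
    v <- rep(NA_real_, max(rows$end))
    for (i in seq_len(nrow(rows))) {
      v[(rows$start[i] + 1L):rows$end[i]] <- rows$score[i]
    }
    scores[[ch]] <- v
  }
  conservation_track(scores)
}

#' Write a conservation track as bedGraph
#' @param track A `cons_track`.
#' @param path Output path.
#' @export
write_bedgraph_track <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$scores)) {
    v <- track$scores[[ch]]
    r <- rle(ifelse(is.na(v), NA_real_, round(v, 6)))
    ends <- cumsum(r$lengths)
    starts0 <- ends - r$lengths  # bedGraph 0-based starts
    keep <- !is.na(r$values)
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%g", ch, starts0[keep], ends[keep],
                         r$values[keep]), con)
    }
  }
  invisible(path)
}

#' Score lookup in a conservation track
#'
#' @param track A `cons_track`.
#' @param chrom Chromosome name (scalar).
#' @param pos Vector of 1-based positions.
#' @return Numeric vector of scores; `NA` where the track has no data.
#' @export
track_score <- function(track, chrom, pos) {
  v <- track$scores[[chrom]]
  if (is.null(v)) return(rep(NA_real_, length(pos)))
  out <- rep(NA_real_, length(pos))
  ok <- pos >= 1 & pos <= length(v)
  out[ok] <- v[pos[ok]]
  out
}

#' Read annotation intervals from BED
#'
#' BED is 0-based half-open; coordinates are converted to the package's
#' 1-based inclusive convention on read.
#'
#' @param path BED file (>= 3 columns).
#' @return Tibble with columns `chrom`, `start`, `end` (1-based inclusive),
#'   and, when present in the file, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character")
  out <- tibble::tibble(
    chrom = bed[[1]],
    start = as.integer(bed[[2]]) + 1L,
    end = as.integer(bed[[3]])
  )
  if (ncol(bed) >= 4) out$name <- bed[[4]]
  if (ncol(bed) >= 5) out$score <- as.numeric(bed[[5]])
  if (ncol(bed) >= 6) out$strand <- bed[[6]]
  out
}

#' Export skipping events as BED plus a junction TSV
#'
#' The BED interval is the cassette exon (converted to 0-based half-open),
#' name = event id, score = 0. A companion TSV carries the three junction
#' coordinate pairs.
#'
#' @param events Event tibble from [enumerate_triplets()].
#' @param bed_path Output BED path.
#' @param tsv_path Optional output TSV path for the junction coordinates.
#' @export
write_events_bed <- function(events, bed_path, tsv_path = NULL) {
  strand <- ifelse(events$strand == "*", ".", events$strand)
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   events$chrom, events$exon_start - 1L, events$exon_end,
                   events$event_id, strand)
  writeLines(lines, bed_path)
  if (!is.null(tsv_path)) {
    readr::write_tsv(events[c("event_id", "chrom", "strand",
                              "uj_start", "uj_end", "dj_start", "dj_end",
                              "sj_start", "sj_end")], tsv_path)
  }
  invisible(bed_path)
}
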