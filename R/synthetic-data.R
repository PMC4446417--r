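#' Design of a synthetic matched tumor/normal splicing cohort
#'
#' Bundles every knob of the generator: cohort shape (cancer types, matched
#' pairs per type), event structure (counts, exon/intron length ranges,
#' frame-preserving fraction), the planted differential-splicing signal
#' (number of altered events, effect size, cross-type coherence), the
#' sequencing-depth and PSI-noise model, the planted motif signal, and the
#' conservation-track levels. The defaults describe the reference cohort
#' used throughout the package's validation: 3 cancer types of 20 matched
#' pairs, 1000 cassette events of which 100 carry a |dPSI| = 0.25 effect at
#' mean junction depth 50, a TGCATG motif planted in downstream introns of
#' tumor-included altered exons at 60% versus 10% background, and a
#' conservation track at 0.9 over planted motif bases versus 0.4 baseline.
#'
#' @param cancer_types Cancer-type labels.
#' @param pairs_per_type Matched tumor/normal pairs per cancer type.
#' @param n_events Number of cassette loci.
#' @param n_altered Number of events with a planted tumor effect.
#' @param delta_psi_effect Absolute planted PSI shift (tumor - normal).
#' @param coherent_fraction Fraction of altered events whose planted sign is
#'   shared across all cancer types; the rest flip sign in one random type.
#' @param depth_mean Mean per-event junction depth; per event-sample depth
#'   is Gamma(`depth_shape`) around it.
#' @param depth_shape Gamma shape of the depth draw.
#' @param jitter_scale,jitter_shape Per-sample biological PSI jitter:
#'   `(Beta(shape, shape) - 0.5) * scale` added to the true PSI, clamped to
#'   `[0, 1]`.
#' @param motif_plant List: `kmer`, `region` (`upstream_intron` /
#'   `downstream_intron`), `direction` (`included` / `excluded`), `fg_rate`,
#'   `bg_rate`.
#' @param flank_len Flanking-intron window (nt) the motif is planted in.
#' @param exon_len,intron_len Length ranges (nt) for cassette exons and
#'   introns; introns are never shorter than `flank_len`.
#' @param frame_frac Fraction of exons whose length is rounded to a multiple
#'   of 3.
#' @param outer_exon_len,locus_gap Constitutive-exon length and inter-locus
#'   spacing (nt).
#' @param chrom Synthetic chromosome name.
#' @param chrom_len Optional fixed chromosome length; error if the loci do
#'   not fit. `NULL` sizes the chromosome to the loci.
#' @param cons_base,cons_motif,cons_noise_sd Conservation-track baseline,
#'   planted-motif level, and Gaussian noise sd.
#' @param seed Integer seed; every generator draw derives from it.
#' @return A `cohort_design` list.
#' @export
cohort_design <- function(cancer_types = c("BRCA", "LUAD", "KIRC"),
                          pairs_per_type = 20,
                          n_events = 1000,
                          n_altered = 100,
                          delta_psi_effect = 0.25,
                          coherent_fraction = 0.8,
                          depth_mean = 50,
                          depth_shape = 10,
                          jitter_scale = 0.1,
                          jitter_shape = 5,
                          motif_plant = list(kmer = "TGCATG",
                                             region = "downstream_intron",
                                             direction = "included",
                                             fg_rate = 0.6, bg_rate = 0.1),
                          flank_len = 250,
                          exon_len = c(30, 150),
                          intron_len = c(300, 800),
                          frame_frac = 0.7,
                          outer_exon_len = 100,
                          locus_gap = 200,
                          chrom = "chrS",
                          chrom_len = NULL,
                          cons_base = 0.4,
                          cons_motif = 0.9,
                          cons_noise_sd = 0.05,
                          seed = 1) {
  d <- structure(as.list(environment()), class = "cohort_design")
  if (d$n_altered > d$n_events) stop("n_altered must be <= n_events")
  rates <- c(d$coherent_fraction, d$frame_frac,
             d$motif_plant$fg_rate, d$motif_plant$bg_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (d$depth_mean < 0) stop("depth_mean must be >= 0")
  if (min(d$intron_len) < d$flank_len) {
    stop("intron_len must be >= flank_len so flank windows stay intronic")
  }
  d
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("<cohort_design> ", length(x$cancer_types), " cancer type(s) x ",
      x$pairs_per_type, " pairs; ", x$n_events, " events (", x$n_altered,
      " altered at |dPSI| = ", x$delta_psi_effect, "), depth ", x$depth_mean,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Generate cassette-exon gene models and a synthetic genome
#'
#' Lays out `n_events` non-overlapping cassette loci along one synthetic
#' chromosome — constitutive exon, upstream intron, cassette exon,
#' downstream intron, constitutive exon — with random strands and lengths
#' drawn from the design's ranges, and (optionally) a uniform-random
#' nucleotide sequence. Deterministic for a fixed design seed.
#'
#' @param design A `cohort_design`.
#' @param sequence Generate the genome sequence (set `FALSE` when only
#'   coordinates and counts are needed).
#' @return List with `events` (the standard event tibble) and `genome`
#'   (a [Biostrings::DNAStringSet], or `NULL` when `sequence = FALSE`).
#' @export
generate_gene_models <- function(design, sequence = TRUE) {
  set.seed(design$seed)
  n <- design$n_events
  if (n == 0) {
    ev <- enumerate_triplets(tibble::tibble(chrom = character(),
                                            start = integer(),
                                            end = integer(),
                                            strand = character()))
    genome <- if (sequence) Biostrings::DNAStringSet(stats::setNames("", design$chrom))
    return(list(events = ev, genome = genome))
  }
  rint <- function(lo, hi, n) {           # sample() misbehaves on scalar ranges
    v <- seq.int(lo, hi)
    v[sample.int(length(v), n, replace = TRUE)]
  }
  elen <- rint(design$exon_len[1], design$exon_len[2], n)
  to_frame <- stats::runif(n) < design$frame_frac
  elen[to_frame] <- pmax(3L, as.integer(round(elen[to_frame] / 3) * 3))
  ilen1 <- rint(design$intron_len[1], design$intron_len[2], n)
  ilen2 <- rint(design$intron_len[1], design$intron_len[2], n)
  strand <- sample(c("+", "-"), n, replace = TRUE)

  outer <- design$outer_exon_len
  locus_len <- 2L * outer + ilen1 + elen + ilen2
  locus_start <- design$locus_gap +
    cumsum(c(0L, (locus_len + design$locus_gap)[-n])) + 1L
  uj_start <- locus_start + outer
  uj_end <- uj_start + ilen1 - 1L
  exon_start <- uj_end + 1L
  exon_end <- exon_start + elen - 1L
  dj_start <- exon_end + 1L
  dj_end <- dj_start + ilen2 - 1L
  total_len <- locus_start[n] + locus_len[n] - 1L + design$locus_gap
  if (!is.null(design$chrom_len)) {
    if (total_len > design$chrom_len) {
      stop("loci do not fit into chrom_len = ", design$chrom_len,
           " (need ", total_len, ")")
    }
    total_len <- design$chrom_len
  }

  events <- tibble::tibble(
    event_id = sprintf("%s:%d-%d|%d-%d", design$chrom, uj_start, uj_end,
                       dj_start, dj_end),
    chrom = design$chrom, strand = strand,
    uj_start = uj_start, uj_end = uj_end,
    dj_start = dj_start, dj_end = dj_end,
    sj_start = uj_start, sj_end = dj_end,
    exon_start = exon_start, exon_end = exon_end,
    exon_length = elen
  )
  genome <- NULL
  if (sequence) {
    bases <- sample(c("A", "C", "G", "T"), total_len, replace = TRUE)
    genome <- Biostrings::DNAStringSet(
      stats::setNames(paste(bases, collapse = ""), design$chrom))
  }
  list(events = events, genome = genome)
}

#' Plant ground-truth PSI levels and effects
#'
#' Draws a baseline inclusion level per event and assigns `n_altered` events
#' a tumor shift of exactly `delta_psi_effect` in magnitude. A fraction
#' `coherent_fraction` of altered events keeps one sign across all cancer
#' types; the rest flip sign in one randomly chosen type (non-coherent).
#' Baselines of altered events are drawn so the shifted PSI stays inside
#' `[0.05, 0.95]` without clamping.
#'
#' @param design A `cohort_design`.
#' @param events Event tibble from [generate_gene_models()].
#' @return Long truth tibble: `event_id`, `cancer_type`, `altered`,
#'   `psi_normal`, `psi_tumor`, `direction` (`inclusion` / `exclusion` /
#'   `NA`), `coherence` (planted label: `coherent` / `non_coherent` / `NA`).
#' @export
simulate_truth <- function(design, events) {
  set.seed(design$seed + 1L)
  n <- nrow(events)
  types <- design$cancer_types
  delta <- design$delta_psi_effect
  altered_idx <- sort(sample.int(n, design$n_altered))
  altered <- seq_len(n) %in% altered_idx

  psi_normal <- numeric(n)
  psi_normal[!altered] <- stats::runif(sum(!altered), 0.05, 0.95)
  psi_normal[altered] <- stats::runif(sum(altered), 0.05 + delta, 0.95 - delta)

  base_sign <- integer(n)
  base_sign[altered] <- sample(c(1L, -1L), sum(altered), replace = TRUE)
  n_coh <- round(design$coherent_fraction * design$n_altered)
  coh_events <- altered_idx[seq_len(n_coh)]
  noncoh_events <- setdiff(altered_idx, coh_events)

  sign_mat <- matrix(0L, n, length(types),
                     dimnames = list(events$event_id, types))
  sign_mat[altered, ] <- base_sign[altered]
  if (length(types) >= 2) {
    for (i in noncoh_events) {
      flip <- sample.int(length(types), 1L)
      sign_mat[i, flip] <- -sign_mat[i, flip]
    }
  }
  coherence <- rep(NA_character_, n)
  coherence[coh_events] <- "coherent"
  coherence[noncoh_events] <-
    if (length(types) >= 2) "non_coherent" else "coherent"

  truth <- tidyr::expand_grid(idx = seq_len(n), cancer_type = types)
  truth$event_id <- events$event_id[truth$idx]
  truth$altered <- altered[truth$idx]
  truth$psi_normal <- psi_normal[truth$idx]
  s <- sign_mat[cbind(truth$idx, match(truth$cancer_type, types))]
  truth$psi_tumor <- truth$psi_normal + s * delta
  truth$direction <- dplyr::case_when(s > 0 ~ "inclusion",
                                      s < 0 ~ "exclusion",
                                      TRUE ~ NA_character_)
  truth$coherence <- coherence[truth$idx]
  truth[c("event_id", "cancer_type", "altered", "psi_normal", "psi_tumor",
          "direction", "coherence")]
}

#' Draw junction read counts for one true inclusion level
#'
#' The generator's evidence model: given a resolved per-sample PSI `pi` and
#' depth `d`, the inclusion junctions draw independently
#' `UJC, DJC ~ Poisson(d * pi)` and the skipping junction
#' `SJC ~ Poisson(d * (1 - pi))`, so the PSI estimator is consistent as `d`
#' grows.
#'
#' @param pi True inclusion level(s) in `[0, 1]` (vectorized).
#' @param depth Per-draw depth(s).
#' @return Tibble with columns `ujc`, `djc`, `sjc`.
#' @export
simulate_event_counts <- function(pi, depth) {
  stopifnot(all(pi >= 0 & pi <= 1), all(depth >= 0))
  n <- max(length(pi), length(depth))
  pi <- rep_len(pi, n); depth <- rep_len(depth, n)
  tibble::tibble(
    ujc = stats::rpois(n, depth * pi),
    djc = stats::rpois(n, depth * pi),
    sjc = stats::rpois(n, depth * (1 - pi))
  )
}

#' Simulate per-sample junction count tables for a cohort
#'
#' Builds the manifest (one tumor and one normal sample per patient per
#' cancer type) and, for every event-sample cell, resolves the true PSI from
#' the truth table, adds the design's Beta jitter, draws a Gamma depth
#' around `depth_mean`, and samples the three junction counts via
#' [simulate_event_counts()]'s model.
#'
#' @param design A `cohort_design`.
#' @param events Event tibble.
#' @param truth Truth tibble from [simulate_truth()].
#' @return List with `manifest` and `junction_counts` (long tibble:
#'   `sample_id`, `chrom`, `start`, `end`, `strand`, `count`).
#' @export
simulate_counts <- function(design, events, truth) {
  set.seed(design$seed + 2L)
  manifest <- make_manifest(design)
  n_ev <- nrow(events)
  rows <- lapply(seq_len(nrow(manifest)), function(si) {
    samp <- manifest[si, ]
    tt <- truth[truth$cancer_type == samp$cancer_type, ]
    tt <- tt[match(events$event_id, tt$event_id), ]
    pi0 <- if (samp$condition == "tumor") tt$psi_tumor else tt$psi_normal
    eps <- (stats::rbeta(n_ev, design$jitter_shape, design$jitter_shape) - 0.5) *
      design$jitter_scale
    pi_s <- pmin(1, pmax(0, pi0 + eps))
    d <- if (design$depth_mean > 0) {
      stats::rgamma(n_ev, shape = design$depth_shape,
                    rate = design$depth_shape / design$depth_mean)
    } else {
      rep(0, n_ev)
    }
    cnt <- simulate_event_counts(pi_s, d)
    tibble::tibble(
      sample_id = samp$sample_id,
      chrom = rep(events$chrom, 3L),
      start = c(events$uj_start, events$dj_start, events$sj_start),
      end = c(events$uj_end, events$dj_end, events$sj_end),
      strand = rep(events$strand, 3L),
      count = c(cnt$ujc, cnt$djc, cnt$sjc)
    )
  })
  jc <- dplyr::bind_rows(rows)
  # SJ shares coordinates with no inner junction, but UJ/DJ of different
  # events can coincide only if loci overlapped (they never do here)
  list(manifest = manifest, junction_counts = jc)
}

make_manifest <- function(design) {
  grid <- tidyr::expand_grid(cancer_type = design$cancer_types,
                             pair = seq_len(design$pairs_per_type),
                             condition = c("tumor", "normal"))
  tibble::tibble(
    sample_id = sprintf("%s_P%02d_%s", grid$cancer_type, grid$pair,
                        ifelse(grid$condition == "tumor", "T", "N")),
    patient_id = sprintf("%s_P%02d", grid$cancer_type, grid$pair),
    condition = grid$condition,
    cancer_type = grid$cancer_type
  )
}

#' Plant splicing-factor motifs into the synthetic genome
#'
#' Writes the design's k-mer at a uniform-random offset inside the
#' configured flanking-intron window: with probability `fg_rate` for
#' foreground events (altered events whose planted direction matches the
#' configured direction in at least one cancer type), and with probability
#' `bg_rate` for all other events. On `-` strand loci the reverse complement
#' is written so the transcription-orientation window reads the k-mer.
#'
#' @param genome Named [Biostrings::DNAStringSet] or named character vector.
#' @param events Event tibble.
#' @param truth Truth tibble (defines the foreground).
#' @param design A `cohort_design` (uses `motif_plant`, `flank_len`,
#'   `seed`).
#' @return List with `genome` (modified) and `planted` (tibble: `event_id`,
#'   `region`, `chrom`, `start`, `end`, `strand`, `is_fg`).
#' @export
plant_motifs <- function(genome, events, truth, design) {
  set.seed(design$seed + 3L)
  mp <- design$motif_plant
  klen <- nchar(mp$kmer)
  fg_dir <- c(included = "inclusion", excluded = "exclusion")[[mp$direction]]
  fg_ids <- unique(truth$event_id[truth$altered &
                                    !is.na(truth$direction) &
                                    truth$direction == fg_dir])
  ev <- events[events$strand != "*", ]
  windows <- region_windows(ev, mp$region, design$flank_len)
  if (any(windows$end - windows$start + 1L < klen)) {
    stop("motif window shorter than the k-mer")
  }
  is_fg <- windows$event_id %in% fg_ids
  rate <- ifelse(is_fg, mp$fg_rate, mp$bg_rate)
  plant <- stats::runif(nrow(windows)) < rate

  chroms <- if (is.character(genome)) genome else {
    stats::setNames(as.character(genome), names(genome))
  }
  planted <- windows[plant, ]
  is_fg <- is_fg[plant]
  if (nrow(planted) > 0) {
    wlen <- planted$end - planted$start + 1L
    off <- floor(stats::runif(nrow(planted)) * (wlen - klen + 1L)) + 1L
    neg <- planted$strand == "-"
    g_start <- integer(nrow(planted))
    g_start[!neg] <- planted$start[!neg] + off[!neg] - 1L
    g_start[neg] <- planted$end[neg] - off[neg] + 1L - klen + 1L
    g_end <- g_start + klen - 1L
    ins <- ifelse(neg, reverse_complement(mp$kmer), mp$kmer)
    for (i in seq_len(nrow(planted))) {
      ch <- planted$chrom[i]
      substr(chroms[[ch]], g_start[i], g_end[i]) <- ins[i]
    }
    planted$start <- g_start
    planted$end <- g_end
  }
  planted$is_fg <- is_fg
  list(genome = Biostrings::DNAStringSet(chroms),
       planted = planted[c("event_id", "region", "chrom", "start", "end",
                           "strand", "is_fg")])
}

# genomic window of one region type, transcription-aware (coordinates only)
region_windows <- function(ev, region, flank) {
  uj_len <- ev$uj_end - ev$uj_start + 1L
  dj_len <- ev$dj_end - ev$dj_start + 1L
  uj_ws <- ev$uj_end - pmin(flank, uj_len) + 1L
  dj_we <- ev$dj_start + pmin(flank, dj_len) - 1L
  plus <- ev$strand == "+"
  if (region == "exon") {
    start <- ev$exon_start; end <- ev$exon_end
  } else if (region == "upstream_intron") {
    start <- ifelse(plus, uj_ws, ev$dj_start)
    end <- ifelse(plus, ev$uj_end, dj_we)
  } else if (region == "downstream_intron") {
    start <- ifelse(plus, ev$dj_start, uj_ws)
    end <- ifelse(plus, dj_we, ev$uj_end)
  } else {
    stop("unknown region '", region, "'")
  }
  tibble::tibble(event_id = ev$event_id, region = region, chrom = ev$chrom,
                 start = as.integer(start), end = as.integer(end),
                 strand = ev$strand)
}

#' Build the synthetic conservation track
#'
#' Baseline score plus Gaussian noise everywhere data exists, elevated to
#' the motif level (plus noise) over planted motif bases; all scores are
#' clamped to `[0, 1]`. By default only the loci's exon and flank windows
#' (padded by 100 nt) carry data, mimicking a patchy real track.
#'
#' @param genome Named [Biostrings::DNAStringSet] or named character vector.
#' @param planted Planted-motif tibble from [plant_motifs()].
#' @param design A `cohort_design` (uses `cons_base`, `cons_motif`,
#'   `cons_noise_sd`, `seed`).
#' @param windows Optional tibble (`chrom`, `start`, `end`) restricting
#'   where the track has data; `NULL` covers whole chromosomes.
#' @return A `cons_track`.
#' @export
make_conservation_track <- function(genome, planted, design, windows = NULL) {
  set.seed(design$seed + 4L)
  lens <- if (is.character(genome)) nchar(genome) else Biostrings::width(genome)
  names(lens) <- names(genome)
  scores <- list()
  for (ch in names(lens)) {
    v <- rep(NA_real_, lens[[ch]])
    if (is.null(windows)) {
      cover <- rep(TRUE, lens[[ch]])
    } else {
      w <- windows[windows$chrom == ch, ]
      cover <- rep(FALSE, lens[[ch]])
      for (i in seq_len(nrow(w))) {
        cover[max(1L, w$start[i] - 100L):min(lens[[ch]], w$end[i] + 100L)] <- TRUE
      }
    }
    n_cov <- sum(cover)
    v[cover] <- design$cons_base + stats::rnorm(n_cov, 0, design$cons_noise_sd)
    pl <- planted[planted$chrom == ch, ]
    for (i in seq_len(nrow(pl))) {
      idx <- pl$start[i]:pl$end[i]
      v[idx] <- design$cons_motif +
        stats::rnorm(length(idx), 0, design$cons_noise_sd)
    }
    scores[[ch]] <- pmin(1, pmax(0, v))
  }
  conservation_track(scores)
}

#' Simulate a complete cohort in memory
#'
#' Runs the whole generator: gene models (+ genome), truth table, manifest
#' and junction counts, planted motifs, and conservation track. Fully
#' reproducible from the design (which carries the seed).
#'
#' @param design A `cohort_design`.
#' @param with_genome Generate sequence, motif plants and the conservation
#'   track (set `FALSE` for count-only cohorts; much faster).
#' @return List: `design`, `events`, `truth`, `manifest`,
#'   `junction_counts`, and — when `with_genome` — `genome`, `planted`,
#'   `track`.
#' @export
simulate_cohort <- function(design, with_genome = TRUE) {
  gm <- generate_gene_models(design, sequence = with_genome)
  truth <- simulate_truth(design, gm$events)
  cnt <- simulate_counts(design, gm$events, truth)
  out <- list(design = design, events = gm$events, truth = truth,
              manifest = cnt$manifest, junction_counts = cnt$junction_counts)
  if (with_genome) {
    pm <- plant_motifs(gm$genome, gm$events, truth, design)
    win <- dplyr::bind_rows(
      region_windows(gm$events, "exon", design$flank_len),
      region_windows(gm$events, "upstream_intron", design$flank_len),
      region_windows(gm$events, "downstream_intron", design$flank_len)
    )
    out$genome <- pm$genome
    out$planted <- pm$planted
    out$track <- make_conservation_track(pm$genome, pm$planted, design,
                                         windows = win)
  }
  out
}

#' Write a simulated cohort as a file tree
#'
#' Emits exactly the formats the readers consume: one SJ.out.tab-dialect
#' file per sample under `sj/`, `manifest.tsv`, `genome.fa`,
#' `conservation.bedGraph`, the truth tables (`truth.tsv`,
#' `events_truth.tsv`, `planted_motifs.tsv`) and a `files.tsv` manifest of
#' relative paths. On any failure the partially written directory is
#' removed.
#'
#' @param design A `cohort_design`.
#' @param out_dir Output directory (created; must not already contain a
#'   cohort).
#' @return Invisibly, the in-memory cohort list with `$paths` attached.
#' @export
write_cohort <- function(design, out_dir) {
  created <- !dir.exists(out_dir)
  if (created) dir.create(out_dir, recursive = TRUE)
  tryCatch({
    cohort <- simulate_cohort(design, with_genome = TRUE)
    sj_dir <- file.path(out_dir, "sj")
    dir.create(sj_dir, showWarnings = FALSE)
    sj_files <- character(0)
    for (s in cohort$manifest$sample_id) {
      tbl <- cohort$junction_counts[cohort$junction_counts$sample_id == s, ]
      f <- file.path("sj", paste0(s, ".sj.tab"))
      write_sj_table(tbl, file.path(out_dir, f))
      sj_files <- c(sj_files, f)
    }
    readr::write_tsv(cohort$manifest, file.path(out_dir, "manifest.tsv"))
    Biostrings::writeXStringSet(cohort$genome, file.path(out_dir, "genome.fa"))
    write_bedgraph_track(cohort$track, file.path(out_dir, "conservation.bedGraph"))
    readr::write_tsv(cohort$truth, file.path(out_dir, "truth.tsv"))
    readr::write_tsv(cohort$events, file.path(out_dir, "events_truth.tsv"))
    readr::write_tsv(cohort$planted, file.path(out_dir, "planted_motifs.tsv"))
    paths <- tibble::tibble(
      kind = c(rep("sj", length(sj_files)), "manifest", "genome",
               "conservation", "truth", "events_truth", "planted_motifs"),
      path = c(sj_files, "manifest.tsv", "genome.fa", "conservation.bedGraph",
               "truth.tsv", "events_truth.tsv", "planted_motifs.tsv")
    )
    readr::write_tsv(paths, file.path(out_dir, "files.tsv"))
    cohort$paths <- paths
    invisible(cohort)
  }, error = function(e) {
    if (created) unlink(out_dir, recursive = TRUE)
    stop("cohort write failed (directory cleaned): ",
         conditionMessage(e), call. = FALSE)
  })
}
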