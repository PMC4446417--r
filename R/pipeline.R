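#' Pipeline run configuration
#'
#' Collects the input paths, output directory and every analysis threshold.
#' All thresholds default to the values used throughout the package:
#' junction support 5 reads, balance rule `|UJC - DJC| < 10` or
#' `< 2 min(UJC, DJC)`, coverage `>= 10` in `>= 15` matched pairs,
#' differential FDR 0.05 with `|mean dPSI| >= 0.10`, marker rule
#' `|dPSI| >= 0.10` in `>= 90%` of pairs, 250-nt flanks, motif FDR 0.01
#' over k-mers of length 4-6.
#'
#' @param sj_dir Directory of per-sample SJ tables (`*.tab` / `*.tsv` /
#'   `*.sj.tab`); the sample id is the file name up to the first dot.
#' @param manifest Path to the manifest TSV.
#' @param out_dir Output directory for stage TSVs.
#' @param fasta Optional genome FASTA (enables the motif stage).
#' @param conservation Optional bedGraph track (enables profiles).
#' @param annotation Optional BED of annotation intervals.
#' @param motif_table Optional motif-to-factor TSV.
#' @param min_reads,max_abs_diff,ratio_mult Discovery thresholds.
#' @param min_cov,min_pairs High-expression filter thresholds.
#' @param fdr,min_delta Differential-calling thresholds.
#' @param marker_delta,marker_frac Marker-detection thresholds.
#' @param flank,motif_fdr,k,half_window Motif/profile parameters.
#' @param seed Integer seed for any randomized step.
#' @return A `run_config` list.
#' @export
run_config <- function(sj_dir, manifest, out_dir,
                       fasta = NULL, conservation = NULL, annotation = NULL,
                       motif_table = NULL,
                       min_reads = 5, max_abs_diff = 10, ratio_mult = 2,
                       min_cov = 10, min_pairs = 15,
                       fdr = 0.05, min_delta = 0.10,
                       marker_delta = 0.10, marker_frac = 0.90,
                       flank = 250, motif_fdr = 0.01, k = 4:6,
                       half_window = 50, seed = 1) {
  cfg <- structure(as.list(environment()), class = "run_config")
  thr <- c(cfg$min_reads, cfg$max_abs_diff, cfg$ratio_mult, cfg$min_cov,
           cfg$min_pairs, cfg$flank, cfg$half_window)
  if (any(thr <= 0)) stop("thresholds must be positive")
  rates <- c(cfg$fdr, cfg$motif_fdr, cfg$marker_frac)
  if (any(rates <= 0 | rates > 1)) stop("fdr/fraction parameters must be in (0, 1]")
  cfg
}

#' Read a flat key=value pipeline configuration file
#'
#' Lines of the form `key = value` (one per line, `#` comments allowed);
#' keys match the arguments of [run_config()]. `k` may be a comma-separated
#' list.
#'
#' @param path Config file path.
#' @param ... Overrides applied after the file is read.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[[`, character(1), 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), character(1)))
  args <- stats::setNames(as.list(vals), keys)
  numeric_keys <- c("min_reads", "max_abs_diff", "ratio_mult", "min_cov",
                    "min_pairs", "fdr", "min_delta", "marker_delta",
                    "marker_frac", "flank", "motif_fdr", "half_window", "seed")
  for (key in intersect(names(args), numeric_keys)) {
    args[[key]] <- as.numeric(args[[key]])
  }
  if ("k" %in% names(args)) {
    args$k <- as.integer(strsplit(args$k, ",")[[1]])
  }
  overrides <- list(...)
  args[names(overrides)] <- overrides
  do.call(run_config, args)
}

config_hash <- function(cfg) {
  rlang::hash(cfg[sort(setdiff(names(cfg), "out_dir"))])
}

write_stage_tsv <- function(df, path, hash, n_in = NA, n_out = nrow(df)) {
  con <- file(path, "w")
  writeLines(sprintf("# config_hash=%s n_in=%s n_out=%s", hash, n_in, n_out),
             con)
  close(con)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Run the full splicing-analysis pipeline
#'
#' Executes the stages in order — per-cancer-type event discovery, PSI
#' quantification, paired differential calling, cross-cancer recurrence and
#' marker detection, k-mer motif enrichment (when a genome is supplied) and
#' conservation profiling (when a track is supplied) — writing one TSV per
#' stage into the output directory. Every stage TSV starts with a comment
#' line recording the configuration hash and in/out counts; the filter
#' funnel is also logged to `run_log.txt` and via [message()]. Events are
#' discovered per cancer-type dataset (every filter references "the
#' dataset") and unified by event id for the cross-cancer stages. A stage
#' failure aborts with the stage name; earlier stage outputs remain on disk.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with the main in-memory results (`events`,
#'   `psi`, `calls`, `recurrence`, `markers`, `enrichment`, `profiles`,
#'   `funnel`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  log_lines <- character(0)
  log <- function(...) {
    line <- paste0(...)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- load inputs
  inputs <- stage("load", {
    manifest <- read_manifest(config$manifest)
    files <- list.files(config$sj_dir, pattern = "\\.(tab|tsv)$",
                        full.names = TRUE)
    if (length(files) == 0) stop("no SJ tables found in ", config$sj_dir)
    jc <- dplyr::bind_rows(lapply(files, function(f) {
      read_sj_table(f, sample_id = sub("\\..*$", "", basename(f)))
    }))
    list(manifest = manifest, jc = jc)
  })
  manifest <- inputs$manifest
  jc <- inputs$jc
  types <- unique(manifest$cancer_type)
  log("loaded ", length(unique(jc$sample_id)), " samples, ",
      length(types), " cancer type(s)")

  # -- discovery, per cancer-type dataset, unified by event id
  events <- stage("discover", {
    per_type <- lapply(types, function(ct) {
      samples <- manifest$sample_id[manifest$cancer_type == ct]
      ev <- discover_events(jc, samples = samples,
                            min_reads = config$min_reads,
                            max_abs_diff = config$max_abs_diff,
                            ratio_mult = config$ratio_mult)
      f <- attr(ev, "funnel")
      log("[", ct, "] junctions ", f[["junctions_observed"]],
          " -> supported ", f[["junctions_supported"]],
          " -> triplets ", f[["triplets_enumerated"]],
          " -> balanced events ", f[["events_balanced"]])
      ev
    })
    dplyr::distinct(dplyr::bind_rows(per_type), .data$event_id,
                    .keep_all = TRUE)
  })
  log("unified events across types: ", nrow(events))
  write_stage_tsv(events, file.path(config$out_dir, "events.tsv"), hash)
  write_events_bed(events, file.path(config$out_dir, "events.bed"))

  # -- PSI
  psi <- stage("psi", build_psi_matrix(events, jc, manifest$sample_id))
  write_psi_matrix(psi, file.path(config$out_dir, "psi.tsv"))

  # -- differential calling per cancer type
  calls <- stage("differential", {
    suppressWarnings(
      call_differential(psi, manifest, fdr = config$fdr,
                        min_delta = config$min_delta,
                        min_cov = config$min_cov,
                        min_pairs = config$min_pairs)
    )
  })
  for (ct in types) {
    cc <- calls[calls$cancer_type == ct, ]
    log("[", ct, "] highly expressed events tested: ", nrow(cc),
        "; significant: ", sum(cc$significant))
  }
  if (nrow(calls) == 0) warning("no testable events; differential table is empty")
  write_stage_tsv(calls, file.path(config$out_dir, "differential.tsv"), hash,
                  n_in = nrow(events))

  # -- recurrence + markers
  rec <- stage("recurrence", classify_recurrence(calls))
  rec_flat <- rec[setdiff(names(rec), "delta_by_type")]
  write_stage_tsv(rec_flat, file.path(config$out_dir, "recurrence.tsv"), hash,
                  n_in = sum(calls$significant))
  log("recurrent (>1 type): ", sum(rec$n_types > 1),
      " of ", nrow(rec), " significant events; non-coherent: ",
      sum(rec$coherence == "non_coherent"))
  markers <- stage("markers", {
    dplyr::bind_rows(lapply(types, function(ct) {
      detect_markers(psi, manifest, ct, delta = config$marker_delta,
                     frac = config$marker_frac, min_cov = config$min_cov,
                     min_pairs = config$min_pairs)
    }))
  })
  write_stage_tsv(markers[markers$marker, ],
                  file.path(config$out_dir, "markers.tsv"), hash,
                  n_in = nrow(markers))
  log("splicing markers: ", sum(markers$marker))

  # -- motif enrichment (needs genome)
  enrichment <- NULL
  profiles <- NULL
  if (!is.null(config$fasta)) {
    motif_tbl <- if (is.null(config$motif_table)) default_motif_table() else
      read_motif_table(config$motif_table)
    enrichment <- stage("motifs", {
      genome <- read_genome_fasta(config$fasta)
      regions <- extract_regions(events, genome, flank = config$flank)
      dplyr::bind_rows(lapply(types, function(ct) {
        cc <- calls[calls$cancer_type == ct, ]
        sig <- cc[cc$significant, ]
        if (nrow(sig) == 0) return(NULL)
        fg <- regions[regions$event_id %in% sig$event_id, ]
        fg$direction <- ifelse(
          sig$direction[match(fg$event_id, sig$event_id)] == "inclusion",
          "included", "excluded")
        bg <- regions[regions$event_id %in%
                        setdiff(cc$event_id, sig$event_id), ]
        if (nrow(bg) == 0) return(NULL)
        suppressWarnings(
          enrichment_scan(fg, bg, k = config$k, fdr = config$motif_fdr,
                          cancer_type = ct, motif_table = motif_tbl)
        )
      }))
    })
    if (!is.null(enrichment) && nrow(enrichment) > 0) {
      hits <- enrichment[enrichment$significant, ]
      write_stage_tsv(hits, file.path(config$out_dir, "motif_enrichment.tsv"),
                      hash, n_in = nrow(enrichment))
      log("motif enrichment: ", nrow(hits), " significant k-mer strata of ",
          nrow(enrichment), " tested")
    }

    # -- conservation profiles for the mapped motifs (needs track)
    if (!is.null(config$conservation)) {
      profiles <- stage("profiles", {
        track <- read_bedgraph_track(config$conservation)
        genome <- read_genome_fasta(config$fasta)
        regions <- extract_regions(events, genome, flank = config$flank)
        intron <- regions[regions$region != "exon", ]
        sig_ids <- unique(calls$event_id[calls$significant])
        bg_ids <- setdiff(unique(calls$event_id), sig_ids)
        dplyr::bind_rows(lapply(unique(motif_tbl$motif), function(km) {
          occ <- find_motif_occurrences(intron, km)
          if (nrow(occ) == 0) return(NULL)
          occ$group <- ifelse(occ$event_id %in% sig_ids, "foreground",
                              ifelse(occ$event_id %in% bg_ids, "background",
                                     NA_character_))
          occ <- occ[!is.na(occ$group), ]
          if (nrow(occ) == 0) return(NULL)
          prof <- conservation_profile(occ, track,
                                       half_window = config$half_window)
          prof$motif <- km
          prof
        }))
      })
      if (!is.null(profiles) && nrow(profiles) > 0) {
        write_stage_tsv(profiles,
                        file.path(config$out_dir, "conservation_profile.tsv"),
                        hash)
      }
    }
  }

  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(list(events = events, psi = psi, calls = calls,
                 recurrence = rec, markers = markers,
                 enrichment = enrichment, profiles = profiles,
                 funnel = log_lines))
}
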