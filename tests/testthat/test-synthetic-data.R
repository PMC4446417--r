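small_design <- function(...) {
  args <- list(cancer_types = c("A", "B"), pairs_per_type = 5, n_events = 20,
               n_altered = 5, seed = 11)
  over <- list(...)
  args[names(over)] <- over
  do.call(cohort_design, args)
}

test_that("the generator is deterministic for a fixed seed", {
  d <- small_design()
  g1 <- generate_gene_models(d)
  g2 <- generate_gene_models(d)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$events, g2$events)
  c1 <- simulate_counts(d, g1$events, simulate_truth(d, g1$events))
  c2 <- simulate_counts(d, g2$events, simulate_truth(d, g2$events))
  expect_identical(c1$junction_counts, c2$junction_counts)
})

test_that("gene models honor the configured length ranges", {
  d <- small_design(exon_len = c(30, 30))
  ev <- generate_gene_models(d, sequence = FALSE)$events
  expect_true(all(ev$exon_length == 30L))
  expect_true(all(frame_preserved(ev$exon_length)))
  expect_true(all(ev$uj_end - ev$uj_start + 1L >= d$flank_len))
  # loci do not overlap
  expect_true(all(ev$uj_start[-1] > ev$dj_end[-nrow(ev)]))
  # structural invariants of every generated event
  expect_true(all(ev$exon_start == ev$uj_end + 1L))
  expect_true(all(ev$exon_end == ev$dj_start - 1L))
  # degenerate: zero events
  d0 <- small_design(n_events = 0, n_altered = 0)
  expect_equal(nrow(generate_gene_models(d0)$events), 0L)
  # packing error when the chromosome is too short
  expect_error(generate_gene_models(small_design(chrom_len = 1000)),
               "do not fit")
})

test_that("planted truth has exact effect sizes and coherence labels", {
  d <- small_design(coherent_fraction = 0.6)
  ev <- generate_gene_models(d, sequence = FALSE)$events
  truth <- simulate_truth(d, ev)
  alt <- truth[truth$altered, ]
  expect_equal(length(unique(alt$event_id)), 5L)
  expect_equal(abs(alt$psi_tumor - alt$psi_normal),
               rep(d$delta_psi_effect, nrow(alt)))
  expect_true(all(alt$psi_tumor >= 0 & alt$psi_tumor <= 1))
  # coherent events share one sign across types; non-coherent do not
  by_ev <- split(alt, alt$event_id)
  for (tt in by_ev) {
    s <- sign(tt$psi_tumor - tt$psi_normal)
    if (tt$coherence[1] == "coherent") expect_true(all(s == s[1]))
    else expect_true(length(unique(s)) > 1)
  }
  expect_true(all(is.na(truth$direction[!truth$altered])))
})

test_that("the count model is Poisson around depth * PSI", {
  withr::local_seed(77)
  # degenerate rates
  cnt <- simulate_event_counts(rep(1, 50), rep(40, 50))
  expect_true(all(cnt$sjc == 0))
  expect_true(all(compute_psi(cnt$ujc, cnt$djc, cnt$sjc) == 1))
  cnt0 <- simulate_event_counts(0.5, 0)
  expect_equal(unlist(cnt0), c(ujc = 0L, djc = 0L, sjc = 0L),
               ignore_attr = TRUE)
  expect_true(is.na(compute_psi(cnt0$ujc, cnt0$djc, cnt0$sjc)))
  # estimator recovers the planted inclusion level
  cnt <- simulate_event_counts(rep(0.7, 1000), rep(100, 1000))
  psihat <- compute_psi(cnt$ujc, cnt$djc, cnt$sjc)
  expect_equal(mean(psihat), 0.7, tolerance = 0.01)
})

test_that("PSI estimation error shrinks with depth", {
  withr::local_seed(88)
  mae <- vapply(c(10, 50, 200), function(d) {
    pi <- runif(500, 0.1, 0.9)
    cnt <- simulate_event_counts(pi, rep(d, 500))
    mean(abs(compute_psi(cnt$ujc, cnt$djc, cnt$sjc) - pi), na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(mae) < 0))
})

test_that("motif planting respects rates, windows and strand", {
  d <- small_design(n_events = 40, n_altered = 20, coherent_fraction = 1,
                    motif_plant = list(kmer = "TGCATG",
                                       region = "downstream_intron",
                                       direction = "included",
                                       fg_rate = 1, bg_rate = 0))
  gm <- generate_gene_models(d)
  truth <- simulate_truth(d, gm$events)
  pm <- plant_motifs(gm$genome, gm$events, truth, d)
  fg_ids <- unique(truth$event_id[truth$altered & truth$direction == "inclusion"])
  expect_setequal(pm$planted$event_id, fg_ids)  # fg_rate 1, bg_rate 0
  expect_true(all(pm$planted$is_fg))
  # every planted window contains the k-mer in transcription orientation
  reg <- extract_regions(gm$events, pm$genome, flank = d$flank_len)
  dn <- reg[reg$region == "downstream_intron", ]
  has <- vapply(dn$seq, function(s) grepl("TGCATG", s, fixed = TRUE),
                logical(1))
  expect_true(all(has[dn$event_id %in% fg_ids]))
  # planted coordinates sit inside the downstream window on the genome
  for (i in seq_len(nrow(pm$planted))) {
    ev <- gm$events[gm$events$event_id == pm$planted$event_id[i], ]
    expect_equal(fetch_sequence(pm$genome, ev$chrom, pm$planted$start[i],
                                pm$planted$end[i], ev$strand), "TGCATG")
  }
})

test_that("the conservation track is elevated over planted motif bases", {
  d <- small_design(n_events = 30, n_altered = 15, coherent_fraction = 1,
                    motif_plant = list(kmer = "TGCATG",
                                       region = "downstream_intron",
                                       direction = "included",
                                       fg_rate = 1, bg_rate = 0))
  co <- simulate_cohort(d)
  at_motif <- unlist(lapply(seq_len(nrow(co$planted)), function(i) {
    track_score(co$track, co$planted$chrom[i],
                co$planted$start[i]:co$planted$end[i])
  }))
  expect_gt(mean(at_motif), 0.8)
  away <- track_score(co$track, d$chrom,
                      co$events$exon_start[1]:co$events$exon_end[1])
  expect_lt(mean(away, na.rm = TRUE), 0.5)
})

test_that("written cohorts have the right shape and reproduce bit-for-bit", {
  d <- small_design()
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  co <- write_cohort(d, file.path(dir1, "cohort"))
  write_cohort(d, file.path(dir2, "cohort"))
  sj_files <- list.files(file.path(dir1, "cohort", "sj"))
  expect_equal(length(sj_files), 20L)   # 2 types x 5 pairs x 2 conditions
  man <- read_manifest(file.path(dir1, "cohort", "manifest.tsv"))
  expect_equal(nrow(matched_pairs(man)), 10L)
  # identical trees for the same seed
  rel <- list.files(file.path(dir1, "cohort"), recursive = TRUE)
  for (f in rel) {
    expect_identical(readLines(file.path(dir1, "cohort", f)),
                     readLines(file.path(dir2, "cohort", f)),
                     label = f)
  }
  # round trip: SJ files re-read to the simulated counts
  s1 <- co$manifest$sample_id[1]
  back <- read_sj_table(file.path(dir1, "cohort", "sj", paste0(s1, ".sj.tab")),
                        sample_id = s1)
  orig <- co$junction_counts[co$junction_counts$sample_id == s1, ]
  orig <- orig[order(orig$start), ]
  back <- back[order(back$start), ]
  expect_equal(back$count, orig$count)
})
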