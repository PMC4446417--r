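one_event <- function(uj_start, uj_end, dj_start, dj_end, strand = "+",
                      chrom = "chr1") {
  exon_start <- uj_end + 1L; exon_end <- dj_start - 1L
  tibble::tibble(
    event_id = sprintf("%s:%d-%d|%d-%d", chrom, uj_start, uj_end,
                       dj_start, dj_end),
    chrom = chrom, strand = strand,
    uj_start = uj_start, uj_end = uj_end, dj_start = dj_start,
    dj_end = dj_end, sj_start = uj_start, sj_end = dj_end,
    exon_start = exon_start, exon_end = exon_end,
    exon_length = exon_end - exon_start + 1L
  )
}

rand_genome <- function(len, name = "chr1", seed = 1) {
  withr::with_seed(seed, {
    stats::setNames(paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                          collapse = ""), name)
  })
}

test_that("region windows hug the exon and respect the flank cap", {
  g <- rand_genome(3000)
  # whole introns when shorter than the flank
  ev <- one_event(100L, 199L, 300L, 399L)
  reg <- extract_regions(ev, g, flank = 250)
  up <- reg[reg$region == "upstream_intron", ]
  dn <- reg[reg$region == "downstream_intron", ]
  ex <- reg[reg$region == "exon", ]
  expect_equal(c(up$start, up$end), c(100L, 199L))
  expect_equal(c(dn$start, dn$end), c(300L, 399L))
  expect_equal(c(ex$start, ex$end), c(200L, 299L))
  expect_equal(ex$seq, unname(substr(g, 200, 299)))

  # long upstream intron: the 250-nt slice adjacent to the exon
  ev2 <- one_event(1000L, 1999L, 2100L, 2399L)
  up2 <- extract_regions(ev2, g, flank = 250)
  up2 <- up2[up2$region == "upstream_intron", ]
  expect_equal(c(up2$start, up2$end), c(1750L, 1999L))

  # minus strand: roles swap, sequences reverse-complemented
  ev3 <- one_event(100L, 199L, 300L, 399L, strand = "-")
  reg3 <- extract_regions(ev3, g, flank = 250)
  up3 <- reg3[reg3$region == "upstream_intron", ]
  expect_equal(c(up3$start, up3$end), c(300L, 399L))
  expect_equal(up3$seq, reverse_complement(substr(g, 300, 399)))
  ex3 <- reg3[reg3$region == "exon", ]
  expect_equal(ex3$seq, reverse_complement(substr(g, 200, 299)))

  # unknown strand is skipped with a message
  expect_message(
    reg4 <- extract_regions(one_event(100L, 199L, 300L, 399L, strand = "*"),
                            g),
    "unknown strand")
  expect_equal(nrow(reg4), 0L)
})

test_that("k-mer presence is a set over clean ACGT substrings", {
  expect_true("TGCATG" %in% kmer_presence("TGCATGCATG", 6))
  expect_equal(sum(kmer_presence("TGCATGCATG", 6) == "TGCATG"), 1L)
  expect_equal(kmer_presence("AAAAAA", 6), "AAAAAA")
  expect_false("ACTAAC" %in% kmer_presence("AAAAAA", 6))
  expect_equal(kmer_presence("ACG", 4), character(0))
  expect_equal(kmer_presence("ACGTNACGT", 6), character(0))  # N poisons all 6-mers
  expect_setequal(kmer_presence("ACGTNACGT", 4), "ACGT")
})

test_that("enrichment p-values match hypergeometric tail summation", {
  withr::local_seed(101)
  motif <- "ACTAAC"
  mk_seq <- function(with_motif) {
    s <- paste(sample(c("A", "C", "G"), 60, replace = TRUE), collapse = "")
    if (with_motif) paste0(substr(s, 1, 30), motif, substr(s, 31, 60)) else s
  }
  fg <- tibble::tibble(
    event_id = paste0("f", 1:50), region = "downstream_intron",
    chrom = "chr1", start = 1L, end = 66L, strand = "+",
    seq = vapply(1:50 <= 20, mk_seq, character(1)),
    direction = "included")
  bg <- tibble::tibble(
    event_id = paste0("b", 1:450), region = "downstream_intron",
    chrom = "chr1", start = 1L, end = 66L, strand = "+",
    seq = vapply(1:450 <= 30, mk_seq, character(1)))
  res <- suppressWarnings(enrichment_scan(fg, bg, k = 6))
  row <- res[res$kmer == motif & res$region == "downstream_intron", ]
  expect_equal(row$fg_with, 20L)
  expect_equal(row$bg_with, 30L)
  expect_equal(row$p_value, oracle_hyper_tail(500, 50, 50, 20),
               tolerance = 1e-12)
  expect_true(row$q_value >= row$p_value)
  expect_true(row$significant)
  expect_equal(row$factors, "QKI")
  # all reported p-values agree with the summation oracle
  sub <- res[res$region == "downstream_intron", ]
  for (i in seq_len(nrow(sub))) {
    expect_equal(sub$p_value[i],
                 oracle_hyper_tail(500, sub$fg_with[i] + sub$bg_with[i],
                                   50, sub$fg_with[i]),
                 tolerance = 1e-10)
  }
})

test_that("matched foreground/background frequencies are not significant", {
  withr::local_seed(55)
  motif <- "ACTAAC"
  seq_with <- function() {
    s <- paste(sample(c("A", "C", "G"), 40, replace = TRUE), collapse = "")
    paste0(s, motif)
  }
  seq_without <- function() {
    paste(sample(c("A", "C", "G"), 46, replace = TRUE), collapse = "")
  }
  # 20% motif rate on both sides
  fg <- tibble::tibble(event_id = paste0("f", 1:50), region = "exon",
                       chrom = "c", start = 1L, end = 46L, strand = "+",
                       seq = c(replicate(10, seq_with()),
                               replicate(40, seq_without())),
                       direction = "included")
  bg <- tibble::tibble(event_id = paste0("b", 1:200), region = "exon",
                       chrom = "c", start = 1L, end = 46L, strand = "+",
                       seq = c(replicate(40, seq_with()),
                               replicate(160, seq_without())))
  res <- suppressWarnings(enrichment_scan(fg, bg, k = 6))
  row <- res[res$kmer == motif, ]
  expect_gt(row$p_value, 0.05)
  # k-mers absent from every foreground region are not emitted
  expect_false("TTTTTT" %in% res$kmer)
})

test_that("motif-to-factor mapping handles exact and superstring matches", {
  expect_equal(map_motif_to_factor("TGCATG"), "RBFOX")
  expect_equal(map_motif_to_factor("ACTAAC"), "QKI")
  expect_equal(map_motif_to_factor("AAAAAA"), "")
  expect_equal(map_motif_to_factor("GCATG"), "RBFOX")
  expect_equal(map_motif_to_factor(c("CTAAC", "TTTT")), c("QKI", ""))
  custom <- tibble::tibble(factor = "PTB", motif = "TCTT")
  expect_equal(map_motif_to_factor("TCTTCT", custom), "PTB")
})

test_that("motif occurrences map back to genomic coordinates on both strands", {
  g <- rand_genome(1000, seed = 3)
  ev_plus <- one_event(100L, 399L, 500L, 799L, strand = "+")
  ev_minus <- one_event(100L, 399L, 500L, 799L, strand = "-")
  # write ACTAAC at genomic 150-155 (inside UJ)
  substr(g, 150, 155) <- "ACTAAC"
  reg_p <- extract_regions(ev_plus, g, flank = 250)
  occ_p <- find_motif_occurrences(reg_p[reg_p$region == "upstream_intron", ],
                                  "ACTAAC")
  expect_equal(nrow(occ_p), 1L)
  expect_equal(c(occ_p$start, occ_p$end), c(150L, 155L))
  # on the minus strand the genomic sequence must carry the reverse complement
  substr(g, 150, 155) <- "GTTAGT"  # revcomp(ACTAAC)
  reg_m <- extract_regions(ev_minus, g, flank = 250)
  occ_m <- find_motif_occurrences(reg_m[reg_m$region == "downstream_intron", ],
                                  "ACTAAC")
  expect_equal(nrow(occ_m), 1L)
  expect_equal(c(occ_m$start, occ_m$end), c(150L, 155L))
  expect_equal(fetch_sequence(g, "chr1", occ_m$start, occ_m$end, "-"),
               "ACTAAC")
})

test_that("conservation profiles average scores by relative offset", {
  # constant track -> flat profile
  tr <- conservation_track(list(c1 = rep(0.5, 400)))
  occ <- tibble::tibble(chrom = "c1", start = c(200L, 300L),
                        end = c(205L, 305L), group = "foreground")
  prof <- conservation_profile(occ, tr, half_window = 20)
  expect_equal(nrow(prof), 41L)
  expect_true(all(prof$mean_fg == 0.5))
  expect_true(all(prof$n_fg == 2L))
  expect_true(all(prof$n_bg == 0L))

  # indicator track recovers the motif footprint of a single 6-mer
  v <- rep(0, 400); v[200:205] <- 1
  tr2 <- conservation_track(list(c1 = v))
  occ2 <- tibble::tibble(chrom = "c1", start = 200L, end = 205L,
                         group = "foreground")
  prof2 <- conservation_profile(occ2, tr2, half_window = 10)
  # midpoint = 200 + floor(5/2) = 202; motif spans offsets -2..+3
  expect_equal(prof2$mean_fg[prof2$offset %in% -2:3], rep(1, 6))
  expect_equal(prof2$mean_fg[prof2$offset == -3], 0)
  expect_equal(prof2$mean_fg[prof2$offset == 4], 0)

  # invariant to occurrence ordering
  occ3 <- occ[2:1, ]
  expect_equal(conservation_profile(occ3, tr, half_window = 20), prof)
})
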