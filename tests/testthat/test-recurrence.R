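mk_call <- function(event_id, cancer_type, delta, significant = TRUE) {
  tibble::tibble(event_id = event_id, cancer_type = cancer_type,
                 n_pairs = 20L, mean_delta_psi = delta,
                 p_value = 1e-4, q_value = 1e-3,
                 direction = ifelse(delta > 0, "inclusion", "exclusion"),
                 significant = significant)
}

test_that("recurrence classification follows the sign pattern", {
  calls <- dplyr::bind_rows(
    mk_call("e_coh", "BRCA", 0.20), mk_call("e_coh", "LUAD", 0.15),
    mk_call("e_non", "BRCA", 0.20), mk_call("e_non", "KIRC", -0.15),
    mk_call("e_one", "COAD", -0.30),
    mk_call("e_ns", "BRCA", 0.40, significant = FALSE)
  )
  rec <- classify_recurrence(calls)
  expect_setequal(rec$event_id, c("e_coh", "e_non", "e_one"))
  expect_equal(rec$coherence[rec$event_id == "e_coh"], "coherent")
  expect_equal(rec$n_types[rec$event_id == "e_coh"], 2L)
  expect_equal(rec$coherence[rec$event_id == "e_non"], "non_coherent")
  expect_equal(rec$discordant_types[rec$event_id == "e_non"], "KIRC")
  expect_equal(rec$coherence[rec$event_id == "e_one"], "single")
  wide <- recurrence_table(calls)
  expect_equal(wide$BRCA[wide$event_id == "e_non"], 0.20)
  expect_equal(wide$KIRC[wide$event_id == "e_non"], -0.15)
})

marker_fixture <- function(deltas_by_event, n_pairs = 10) {
  man <- pair_manifest(n_pairs)
  pairs <- matched_pairs(man)
  samples <- c(pairs$tumor_sample, pairs$normal_sample)
  ids <- names(deltas_by_event)
  psiM <- matrix(0.5, length(ids), 2 * n_pairs,
                 dimnames = list(ids, samples))
  for (id in ids) {
    psiM[id, pairs$tumor_sample] <- 0.5 + deltas_by_event[[id]]
  }
  cov <- matrix(50, length(ids), 2 * n_pairs, dimnames = dimnames(psiM))
  list(psi = make_psi_matrix(psiM, cov), man = man)
}

test_that("marker rule: >= 90% of pairs changed in one direction", {
  fx <- marker_fixture(list(
    nine = c(rep(-0.12, 9), 0.02),        # 9/10 down -> marker at boundary
    eight = c(rep(-0.12, 8), 0.02, 0.0),  # 8/10 -> no marker
    split = c(rep(0.12, 5), rep(-0.12, 5)) # 5 up / 5 down -> no marker
  ))
  mk <- detect_markers(fx$psi, fx$man, "CT", min_pairs = 5)
  mk <- mk[match(c("nine", "eight", "split"), mk$event_id), ]
  expect_equal(mk$fraction_changed, c(0.9, 0.8, 0.5))
  expect_equal(mk$marker, c(TRUE, FALSE, FALSE))
  expect_equal(mk$n_pairs_examined, rep(10L, 3))
  expect_equal(mk$n_down[1], 9L)
})

test_that("swapping tumor/normal labels flips mean dPSI, keeps the fraction", {
  withr::local_seed(31)
  deltas <- round(runif(12, -0.4, 0.4), 2)
  fx <- marker_fixture(list(ev = deltas), n_pairs = 12)
  man_swapped <- fx$man
  man_swapped$condition <- ifelse(man_swapped$condition == "tumor",
                                  "normal", "tumor")
  a <- detect_markers(fx$psi, fx$man, "CT", min_pairs = 5)
  b <- detect_markers(fx$psi, man_swapped, "CT", min_pairs = 5)
  expect_equal(b$mean_delta_psi, -a$mean_delta_psi)
  expect_equal(b$fraction_changed, a$fraction_changed)
})

test_that("frame preservation is total exonic length mod 3", {
  expect_true(frame_preserved(84))
  expect_false(frame_preserved(85))
  expect_equal(frame_preserved(c(84, 85, 90)), c(TRUE, FALSE, TRUE))
  expect_true(frame_preserved(list(c(70, 50))))  # 120 summed over two exons
})

test_that("two-proportion chi-square matches the closed 2x2 form", {
  expect_equal(proportion_test(50, 100, 50, 100)$p_value, 1)
  r <- proportion_test(90, 100, 10, 100)
  expect_equal(r$statistic, 128, tolerance = 1e-9)
  expect_lt(r$p_value, 1e-20)
  expect_equal(proportion_test(0, 10, 10, 10)$statistic, 20, tolerance = 1e-9)
  expect_error(proportion_test(0, 10, 0, 10), "exact test")
})

test_that("hypergeometric overlap equals direct tail summation", {
  u <- sprintf("g%03d", 1:100)
  expect_equal(hypergeom_overlap(u, u, u)$p_value, 1)
  a <- u[1:10]; b <- u[6:15]  # overlap 5
  got <- hypergeom_overlap(a, b, u)
  expect_equal(got$overlap, 5L)
  expect_equal(got$p_value, oracle_hyper_tail(100, 10, 10, 5), tolerance = 1e-12)
  expect_error(hypergeom_overlap(c(a, "zzz"), b, u), "subsets")
  # brute force over every draw for a small universe
  withr::local_seed(17)
  for (i in 1:10) {
    N <- sample(6:12, 1); nA <- sample(2:(N - 1), 1); nB <- sample(2:(N - 1), 1)
    uu <- sprintf("i%02d", 1:N)
    A <- sample(uu, nA); B <- sample(uu, nB)
    k <- length(intersect(A, B))
    draws <- utils::combn(N, nA)
    bf <- mean(apply(draws, 2, function(ix) length(intersect(uu[ix], B)) >= k))
    expect_equal(hypergeom_overlap(A, B, uu)$p_value, bf, tolerance = 1e-12)
  }
})

test_that("interval overlap respects 1-based inclusive boundaries", {
  ev <- tibble::tibble(event_id = c("a", "b"), chrom = "chr1",
                       exon_start = c(200L, 200L), exon_end = c(299L, 299L))
  expect_equal(interval_overlap(ev[1, ],
                                tibble::tibble(chrom = "chr1", start = 250L,
                                               end = 350L)), "a")
  # 299 < 300: adjacent but not overlapping
  expect_equal(interval_overlap(ev[1, ],
                                tibble::tibble(chrom = "chr1", start = 300L,
                                               end = 400L)), character(0))
  expect_equal(interval_overlap(ev, tibble::tibble(chrom = character(),
                                                   start = integer(),
                                                   end = integer())),
               character(0))
  # min_frac: annotation covering 50 of 100 exon bases
  ann <- tibble::tibble(chrom = "chr1", start = 250L, end = 299L)
  expect_equal(interval_overlap(ev[1, ], ann, min_frac = 0.5), "a")
  expect_equal(interval_overlap(ev[1, ], ann, min_frac = 0.6), character(0))
})

test_that("PSI-expression and dPSI-dPSI correlations behave", {
  psi <- c(0.1, 0.3, 0.5, 0.7)
  expect_equal(psi_expression_correlation(psi, 2 * psi + 1)$r, 1)
  expect_equal(psi_expression_correlation(psi, -psi)$r, -1)
  expect_warning(r0 <- psi_expression_correlation(psi, rep(2, 4)), "variance")
  expect_true(is.na(r0$r))
  expect_true(psi_expression_correlation(psi, c(0.2, 0.1, 0.25, 0.18))$weak)

  a <- stats::setNames(c(0.1, -0.2, 0.3, 0.05), paste0("e", 1:4))
  expect_equal(delta_psi_correlation(a, a)$r, 1)
  expect_equal(delta_psi_correlation(a, -a)$r, -1)
  expect_equal(delta_psi_correlation(a, a[1:2])$n, 2L)
  expect_true(is.na(delta_psi_correlation(a, a[1:2])$r))
  withr::local_seed(8)
  big_a <- stats::setNames(rnorm(1000), paste0("e", 1:1000))
  big_b <- stats::setNames(rnorm(1000), paste0("e", 1:1000))
  expect_lt(abs(delta_psi_correlation(big_a, big_b)$r), 0.1)
})
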