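# Independent oracles used to validate the package's implementations.
# Each one recomputes the quantity by direct enumeration or summation and is
# deliberately written without reusing any package internals.

# exhaustive scan over all ordered junction triples (UJ, DJ, SJ)
oracle_triplets <- function(junctions) {
  j <- as.data.frame(junctions)
  n <- nrow(j)
  if (n < 3) return(character(0))
  g <- expand.grid(u = seq_len(n), d = seq_len(n), s = seq_len(n))
  ok <- j$chrom[g$u] == j$chrom[g$d] & j$chrom[g$u] == j$chrom[g$s] &
    j$start[g$s] == j$start[g$u] &
    j$end[g$s] == j$end[g$d] &
    j$end[g$u] < j$start[g$d] - 1L
  su <- j$strand[g$u]; sd <- j$strand[g$d]; ss <- j$strand[g$s]
  has_plus <- su == "+" | sd == "+" | ss == "+"
  has_minus <- su == "-" | sd == "-" | ss == "-"
  ok <- ok & !(has_plus & has_minus)
  g <- g[ok, ]
  unique(sprintf("%s:%d-%d|%d-%d", j$chrom[g$u], j$start[g$u], j$end[g$u],
                 j$start[g$d], j$end[g$d]))
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
oracle_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Benjamini-Hochberg step-up by direct recomputation
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# upper-tail hypergeometric by term-by-term summation
oracle_hyper_tail <- function(N, K, n, k) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# random junction set with shared boundaries so triplets actually occur
random_junction_set <- function(n, n_anchors = max(4L, n %/% 6L)) {
  anchors <- sort(sample(seq(10L, 4000L, by = 10L), n_anchors * 2L))
  starts <- sample(anchors, n, replace = TRUE)
  ends <- starts + sample(seq(15L, 900L, by = 5L), n, replace = TRUE)
  # snap some ends onto anchor boundaries to create shared outer boundaries
  snap <- runif(n) < 0.6
  ends[snap] <- vapply(starts[snap], function(s) {
    cand <- anchors[anchors > s + 10L]
    if (length(cand) == 0) s + 100L else sample(cand, 1L)
  }, integer(1))
  unique(tibble::tibble(
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    start = starts, end = ends,
    strand = sample(c("+", "-", "*"), n, replace = TRUE,
                    prob = c(0.45, 0.45, 0.1))
  ))
}

# build a psi_matrix directly from psi/coverage matrices (unit-test shortcut)
make_psi_matrix <- function(psi, coverage, events = NULL) {
  if (is.null(events)) {
    events <- tibble::tibble(event_id = rownames(psi))
  }
  structure(list(psi = psi, coverage = coverage, events = events),
            class = "psi_matrix")
}

# manifest for one cancer type with n matched pairs
pair_manifest <- function(n, cancer_type = "CT") {
  tibble::tibble(
    sample_id = c(sprintf("%s_P%02d_T", cancer_type, 1:n),
                  sprintf("%s_P%02d_N", cancer_type, 1:n)),
    patient_id = rep(sprintf("%s_P%02d", cancer_type, 1:n), 2),
    condition = rep(c("tumor", "normal"), each = n),
    cancer_type = cancer_type
  )
}

# mirror a genome (reverse complement) and remap junction coordinates
mirror_genome <- function(genome) {
  Biostrings::reverseComplement(genome)
}

mirror_coords <- function(start, end, len) {
  list(start = len - end + 1L, end = len - start + 1L)
}

mirror_junctions <- function(jc, chrom_lens) {
  len <- chrom_lens[jc$chrom]
  new_start <- len - jc$end + 1L
  new_end <- len - jc$start + 1L
  out <- jc
  out$start <- as.integer(new_start)
  out$end <- as.integer(new_end)
  out$strand <- chartr("+-", "-+", jc$strand)
  out
}
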