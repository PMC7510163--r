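# Shared fixtures and independent oracles for the test suite.

# Naive windowed Pearson of two 0/1 vectors at each shift (position-by-
# position, via stats::cor) - the reference against which the profile
# engines are checked.
naive_ncc <- function(f, g, shifts) {
  L <- length(f)
  vapply(shifts, function(x) {
    if (L - x < 2) return(NA_real_)
    suppressWarnings(stats::cor(f[seq_len(L - x)], g[seq_len(L - x) + x]))
  }, 0)
}

# Same, restricted to the doubly mappable index set of a mask pair.
naive_mscc <- function(f, g, fm, rm, shifts) {
  L <- length(f)
  vapply(shifts, function(x) {
    i <- which(fm[seq_len(max(L - x, 0))] & rm[seq_len(max(L - x, 0)) + x])
    if (length(i) < 4) return(NA_real_)
    suppressWarnings(stats::cor(f[i], g[i + x]))
  }, 0)
}

# Density object from two 0/1 vectors on a single chromosome.
density_from_bits <- function(f, g, R = 20, chrom = "chr1") {
  gs <- genome_spec(chrom, length(f))
  pos <- list(list(forward = which(f == 1) - 1, reverse = which(g == 1) - 1))
  names(pos) <- chrom
  binary_density(pos, gs, R)
}

# Random binary test instance with both strands populated.
random_instance <- function(L, p = 0.1) {
  f <- stats::rbinom(L, 1, p)
  g <- stats::rbinom(L, 1, p)
  f[sample(L, 2)] <- 1  # guarantee non-degenerate strands
  g[sample(L, 2)] <- 1
  list(f = f, g = g)
}

# A CCProfile with a prescribed merged curve, for metric extraction tests.
profile_from_curve <- function(shifts, merged, R = 50) {
  gs <- genome_spec("chr1", max(shifts) * 10 + 1000)
  p <- strandcc:::new_cc_profile(
    as.integer(shifts),
    r = matrix(merged, ncol = 1, dimnames = list(NULL, "chr1")),
    counts = matrix(1e5, nrow = length(shifts), ncol = 1,
                    dimnames = list(NULL, "chr1")),
    mode = "MSCC", estimator = "exact", read_length = R, genome = gs,
    n_reads = matrix(0, 1, 2, dimnames = list("chr1", c("forward", "reverse"))))
  p$merged <- merged
  p
}

# Brute-force exact-match mappability oracle: an R-mer is uniquely mappable
# iff it occurs exactly once among all R-mers of the sequences and their
# reverse complements (string comparison, no shared code with the package).
brute_force_mappable <- function(seqs, R) {
  rc <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]),
                                                 collapse = ""))
  all_kmers <- unlist(lapply(c(seqs, vapply(seqs, rc, "")), function(s) {
    n <- nchar(s) - R + 1
    if (n < 1) character(0) else
      vapply(seq_len(n), function(i) substr(s, i, i + R - 1), "")
  }))
  lapply(seqs, function(s) {
    n <- nchar(s) - R + 1
    ok <- vapply(seq_len(n), function(i) {
      k <- substr(s, i, i + R - 1)
      sum(all_kmers == k) == 1 && !grepl("N", k)
    }, TRUE)
    c(ok, rep(FALSE, R - 1))
  })
}

# Standard reduced-scale simulation constants used across the suite.
std_params <- function(alpha, M = 1e5, n = 1000, G = 1e7, w = 100, d = 200,
                       R = 50) {
  model_params(G = G, n = n, w = w, d = d, alpha = alpha, M = M, R = R)
}
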