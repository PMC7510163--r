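test_that("site placement yields disjoint in-bounds footprints", {
  gs <- genome_spec("chr1", 10000)
  lay <- simulate_sites(gs, 1, 100, 200, seed = 1)
  reg <- site_regions(lay)$chr1
  expect_equal(unname(reg$E_f[, "end"] - reg$E_f[, "start"]), 100)
  expect_equal(unname(reg$E_g[, "start"] - reg$E_f[, "end"]), 200)
  expect_identical(simulate_sites(gs, 0, 100, 200)$anchors$chr1, numeric(0))
  # brute-force pairwise overlap check across chromosomes and seeds
  gs2 <- genome_spec(c("c1", "c2"), c(40000, 20000))
  for (seed in 1:3) {
    lay2 <- simulate_sites(gs2, 60, 100, 200, seed = seed)
    for (chrom in gs2$names) {
      a <- lay2$anchors[[chrom]]
      fp <- cbind(a, a + 2 * 100 + 200)
      if (nrow(fp) > 1)
        for (i in seq_len(nrow(fp) - 1))
          for (j in (i + 1):nrow(fp))
            expect_true(fp[i, 2] <= fp[j, 1] || fp[j, 2] <= fp[i, 1])
      expect_true(all(a >= 0 & a + 400 <= gs2$lengths[[chrom]]))
    }
    expect_equal(sum(lengths(lay2$anchors)), 60)
  }
  expect_error(simulate_sites(gs, 20, 100, 200), "half the genome")
})

test_that("read allocation follows the signal/noise mixture exactly", {
  gs <- genome_spec("chr1", 50000)
  lay <- simulate_sites(gs, 10, 100, 200, seed = 2)
  pp <- model_params(G = 5e4, n = 10, w = 100, d = 200, alpha = 0.2, M = 1000)
  out <- simulate_reads(lay, pp, seed = 3, keep_reads = TRUE)
  reads <- out$reads
  # deterministic allocation: 100 signal + 400 noise per strand, pre-collapse
  expect_equal(sum(reads$strand == "+"), 500)
  expect_equal(sum(reads$strand == "-"), 500)
  reg <- site_regions(lay)$chr1
  in_regions <- function(pos, m) {
    vapply(pos, function(p) any(p >= m[, "start"] & p < m[, "end"]), TRUE)
  }
  fsig <- in_regions(reads$pos5[reads$strand == "+"], reg$E_f)
  expect_gte(sum(fsig), 100)  # 100 signal reads + any noise landing inside
  # alpha = 1: every 5' end lies inside an enriched region
  p1 <- model_params(G = 5e4, n = 10, w = 100, d = 200, alpha = 1, M = 1000)
  r1 <- simulate_reads(lay, p1, seed = 4, keep_reads = TRUE)$reads
  expect_true(all(in_regions(r1$pos5[r1$strand == "+"], reg$E_f)))
  expect_true(all(in_regions(r1$pos5[r1$strand == "-"], reg$E_g)))
  # alpha = 0: uniform noise, M/2 pre-collapse positions per strand
  p0 <- model_params(G = 5e4, n = 10, w = 100, d = 200, alpha = 0, M = 1000)
  r0 <- simulate_reads(lay, p0, seed = 5, keep_reads = TRUE)$reads
  expect_equal(unname(table(r0$strand)[c("+", "-")]), c(500L, 500L),
               ignore_attr = TRUE)
})

test_that("both strands carry the same pre-collapse read count", {
  gs <- genome_spec(c("c1", "c2"), c(30000, 20000))
  lay <- simulate_sites(gs, 20, 100, 200, seed = 6)
  for (a in c(0, 0.3, 1)) {
    pp <- model_params(G = 5e4, n = 20, w = 100, d = 200, alpha = a, M = 2000)
    r <- simulate_reads(lay, pp, seed = 7, keep_reads = TRUE)$reads
    expect_equal(sum(r$strand == "+"), sum(r$strand == "-"))
    expect_equal(nrow(r), 2000)
  }
})

test_that("matched forward/reverse 5' ends sit exactly d + w apart", {
  gs <- genome_spec("chr1", 1e5)
  lay <- simulate_sites(gs, 25, 100, 200, seed = 8)
  pp <- model_params(G = 1e5, n = 25, w = 100, d = 200, alpha = 1, M = 4000)
  d <- simulate_reads(lay, pp, seed = 9)
  prof <- ncc_profile(d, shifts = 0:400)
  expect_equal(prof$shifts[which.max(prof$merged)], 300)
  expect_lte(dedup_count(d), 4000)  # binarisation collapses duplicates
})

test_that("multinomial allocation draws the split but keeps totals", {
  gs <- genome_spec("chr1", 50000)
  lay <- simulate_sites(gs, 10, 100, 200, seed = 10)
  pp <- model_params(G = 5e4, n = 10, w = 100, d = 200, alpha = 0.2, M = 1000)
  r <- simulate_reads(lay, pp, seed = 11, allocation = "multinomial",
                      keep_reads = TRUE)$reads
  expect_equal(nrow(r), 1000)
  # same seed reproduces, different seed varies
  r2 <- simulate_reads(lay, pp, seed = 11, allocation = "multinomial",
                       keep_reads = TRUE)$reads
  expect_identical(r, r2)
})

test_that("simulated genomes have the requested repeat structure", {
  g0 <- simulate_genome(c(chr1 = 2000), repeat_fraction = 0, seed = 30)
  mk0 <- compute_exact_mappability(g0, 50)
  # verified post hoc for this seed: no repeated 50-mer
  expect_equal(sum(mk0$forward$chr1), 2000 - 49)
  g1 <- simulate_genome(c(chr1 = 2000), repeat_fraction = 1,
                        repeat_unit_length = 20, seed = 31)
  mk1 <- compute_exact_mappability(g1, 50)
  expect_lt(sum(mk1$forward$chr1) / 2000, 0.05)
  gm <- simulate_genome(c(chr1 = 5000), repeat_fraction = 0.4,
                        repeat_unit_length = 120, seed = 32)
  mkm <- compute_exact_mappability(gm, 50)
  zero_frac <- 1 - sum(mkm$forward$chr1) / (5000 - 49)
  expect_gt(zero_frac, 0.15)  # repeats create unmappable stretches
  expect_lt(zero_frac, 0.65)
})

test_that("simulated reads round-trip through SAM output", {
  gs <- genome_spec("chr1", 30000)
  lay <- simulate_sites(gs, 8, 100, 200, seed = 40)
  pp <- model_params(G = 3e4, n = 8, w = 100, d = 200, alpha = 0.5, M = 500)
  out <- simulate_reads(lay, pp, seed = 41, keep_reads = TRUE)
  path <- tempfile(fileext = ".sam")
  write_alignments(out$reads, path, format = "SAM", genome = gs,
                   read_length = 50)
  d2 <- read_alignments(path, gs)
  expect_identical(d2$positions, out$density$positions)
})

test_that("repeat-rich genomes degrade NCC while MSCC stays anchored", {
  # reads whose placement is not uniquely mappable are discarded, as an
  # aligner would discard multi-mappers; the masks then induce a spurious
  # correlation at shift R - 1 in NCC that MSCC conditions away
  g <- simulate_genome(c(chrA = 60000, chrB = 40000), repeat_fraction = 0.45,
                       repeat_unit_length = 150, seed = 5)
  mk <- compute_exact_mappability(g, 50)
  gs <- genome_spec_from_fasta(g)
  pp <- model_params(G = 1e5, n = 30, w = 100, d = 200, alpha = 0.15,
                     M = 8000, R = 50)
  lay <- simulate_sites(gs, 30, 100, 200, seed = 9)
  dens <- simulate_reads(lay, pp, seed = 10)
  pos <- lapply(gs$names, function(ch) {
    p <- dens$positions[[ch]]
    list(forward = p$forward[mk$forward[[ch]][p$forward + 1]],
         reverse = p$reverse[mk$reverse[[ch]][p$reverse + 1]])
  })
  names(pos) <- gs$names
  dfilt <- binary_density(pos, gs, 50)
  pn <- ncc_profile(dfilt, shifts = 0:450)
  pm <- mscc_profile(dfilt, mk, shifts = 0:450)
  # the fragment-length peak survives mappability correction
  expect_lt(abs(estimate_fragment_length(pm, exclude_phantom = FALSE) - 300),
            15)
  # NCC carries a mappability-driven phantom at x = R - 1 that MSCC removes
  phantom_ncc <- pn$merged[pn$shifts == 49]
  phantom_mscc <- pm$merged[pm$shifts == 49]
  expect_gt(phantom_ncc, 2 * max(phantom_mscc, 0))
})
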