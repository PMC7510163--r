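test_that("exact NCC equals the windowed Pearson coefficient", {
  # self-correlation at zero shift
  set.seed(1)
  v <- rbinom(400, 1, 0.2)
  d <- density_from_bits(v, v)
  p <- suppressWarnings(ncc_profile(d, shifts = 0:5))  # r = 1 is clamped
  expect_equal(p$merged[1], 1)
  # an exactly shifted copy correlates perfectly at its shift
  f <- c(1, 0, 0, 1, 0, 1, 0, 0, rep(0, 92))
  g <- c(rep(0, 3), f)[1:100]
  p2 <- suppressWarnings(ncc_profile(density_from_bits(f[1:100], g),
                                     shifts = 0:10))
  expect_equal(p2$merged[4], 1)
  # per-chromosome coefficients match the naive oracle (merging clamps |r|=1)
  expect_equal(unname(p2$r[, 1]), naive_ncc(f[1:100], g, 0:10),
               tolerance = 1e-12)
})

test_that("degenerate windows are undefined, never zero", {
  g <- rbinom(200, 1, 0.3); g[1:2] <- 1
  d <- density_from_bits(rep(0, 200), g)
  expect_error(ncc_profile(d), "both strands")
  # all-ones forward strand has zero variance
  d2 <- density_from_bits(rep(1, 200), g)
  p <- ncc_profile(d2, shifts = 0:10)
  expect_true(all(is.na(p$merged)))
  # counts below 4 are undefined
  f <- rep(0, 30); f[c(3, 9)] <- 1
  p2 <- suppressWarnings(ncc_profile(density_from_bits(f, f), shifts = 0:29))
  expect_true(is.na(p2$merged[30]))  # window of 1 position
})

test_that("sparse and FFT |D_x| engines agree bit-for-bit", {
  set.seed(5)
  for (i in 1:5) {
    L <- sample(500:3000, 1)
    inst <- random_instance(L, p = runif(1, 0.02, 0.3))
    d <- density_from_bits(inst$f, inst$g)
    s <- 0:min(200, L - 10)
    ps <- ncc_profile(d, shifts = s, engine = "sparse")
    pf <- ncc_profile(d, shifts = s, engine = "fft")
    expect_identical(ps$counts, pf$counts)
    expect_equal(ps$r, pf$r, tolerance = 1e-13)
  }
})

test_that("global estimator approximates the exact one for sparse densities", {
  set.seed(9)
  L <- 1e5
  inst <- random_instance(L, p = 0.005)  # M << L
  d <- density_from_bits(inst$f, inst$g)
  s <- 0:100  # x <= L / 1000
  pe <- ncc_profile(d, shifts = s, estimator = "exact")
  pg <- ncc_profile(d, shifts = s, estimator = "global")
  expect_lt(max(abs(pe$merged - pg$merged), na.rm = TRUE), 1e-3)
})

test_that("MSCC with an all-ones mask reproduces NCC", {
  set.seed(2)
  L <- 600
  inst <- random_instance(L, 0.15)
  d <- density_from_bits(inst$f, inst$g, R = 25)
  gs <- genome_spec("chr1", L)
  ones <- mappability_mask(list(chr1 = c(rep(TRUE, L - 24), rep(FALSE, 24))),
                           list(chr1 = rep(TRUE, L)), gs, 25)
  # literal all-ones reverse mask: every shift's index set is the full window
  pm <- mscc_profile(d, ones, shifts = 0:50)
  pn <- ncc_profile(d, shifts = 0:50)
  # beyond the forward-boundary effect the sets coincide exactly
  win <- 1:51
  expect_equal(pm$merged[win],
               naive_mscc(inst$f, inst$g, c(rep(TRUE, L - 24), rep(FALSE, 24)),
                          rep(TRUE, L), 0:50)[win], tolerance = 1e-12)
  # and with a truly unrestricted mask MSCC == NCC at every shift
  full <- mappability_mask(list(chr1 = rep(TRUE, L)),
                           list(chr1 = rep(TRUE, L)), gs, 1)
  d1 <- density_from_bits(inst$f, inst$g, R = 1)
  expect_equal(mscc_profile(d1, full, shifts = 0:50)$merged,
               ncc_profile(d1, shifts = 0:50)$merged, tolerance = 1e-12)
})

test_that("MSCC restricts the Pearson coefficient to doubly mappable sets", {
  set.seed(6)
  L <- 800
  inst <- random_instance(L, 0.12)
  gs <- genome_spec("chr1", L)
  fm <- rbinom(L, 1, 0.5) == 1; fm[(L - 18):L] <- FALSE
  rmv <- derive_reverse_mask(rbinom(L, 1, 0.5) == 1, 20)
  mk <- mappability_mask(list(chr1 = fm), list(chr1 = rmv), gs, 20)
  d <- density_from_bits(inst$f, inst$g, R = 20)
  p <- mscc_profile(d, mk, shifts = 0:100)
  oracle <- naive_mscc(inst$f, inst$g, fm, rmv, 0:100)
  expect_equal(p$merged, oracle, tolerance = 1e-12)
  expect_identical(is.na(p$merged), is.na(oracle))
  # an all-zero mask leaves every shift undefined
  zero <- mappability_mask(list(chr1 = rep(FALSE, L)),
                           list(chr1 = rep(FALSE, L)), gs, 20)
  expect_true(all(is.na(mscc_profile(d, zero, shifts = 0:20)$merged)))
  # read-length mismatch is refused
  expect_error(mscc_profile(density_from_bits(inst$f, inst$g, R = 36), mk),
               "read length")
})

test_that("uniform and dense mask representations are equivalent", {
  set.seed(12)
  L <- 700; R <- 30
  inst <- random_instance(L, 0.1)
  d <- density_from_bits(inst$f, inst$g, R = R)
  gs <- genome_spec("chr1", L)
  dm <- strandcc:::dense_masks(flat_mappability(gs, R), "chr1")
  dense <- mappability_mask(list(chr1 = dm$forward), list(chr1 = dm$reverse),
                            gs, R)
  pu <- mscc_profile(d, flat_mappability(gs, R), shifts = 0:80)
  pd <- mscc_profile(d, dense, shifts = 0:80)
  expect_identical(pu$counts, pd$counts)
  expect_equal(pu$r, pd$r, tolerance = 1e-13)
})

test_that("Fisher r-to-z merging weights chromosomes by count - 3", {
  # single chromosome: merging is the identity
  set.seed(3)
  inst <- random_instance(500, 0.2)
  p <- ncc_profile(density_from_bits(inst$f, inst$g), shifts = 0:20)
  expect_equal(p$merged, unname(p$r[, 1]), tolerance = 1e-12)
  # two chromosomes with identical r merge to the same r
  gs <- genome_spec(c("c1", "c2"), c(500, 500))
  pos <- list(c1 = list(forward = which(inst$f == 1) - 1,
                        reverse = which(inst$g == 1) - 1),
              c2 = list(forward = which(inst$f == 1) - 1,
                        reverse = which(inst$g == 1) - 1))
  d2 <- binary_density(pos, gs, 20)
  p2 <- ncc_profile(d2, shifts = 0:20)
  expect_equal(p2$merged, unname(p2$r[, 1]), tolerance = 1e-12)
  # hand-computed three-step transform for unequal r and weights
  prof <- profile_from_curve(0:1, c(0, 0))
  prof$r <- cbind(c1 = c(0.1, 0.1), c2 = c(0.3, 0.3))
  prof$counts <- cbind(c1 = c(1000, 1000), c2 = c(3000, 3000))
  prof$genome <- genome_spec(c("c1", "c2"), c(4000, 4000))
  merged <- merge_profiles(prof)$merged
  byhand <- tanh((997 * atanh(0.1) + 2997 * atanh(0.3)) / (997 + 2997))
  expect_equal(merged, rep(byhand, 2), tolerance = 1e-14)
  # merged coefficient lies within the contributing range
  expect_true(all(merged >= 0.1 & merged <= 0.3))
})

test_that("|r| = 1 coefficients are clamped before the Fisher transform", {
  f <- c(1, 0, 0, 1, 0, 1, 0, 0, 1, 1, rep(0, 20))
  d <- density_from_bits(f, f)
  expect_warning(p <- ncc_profile(d, shifts = 0:5), "clamped")
  expect_lt(abs(p$merged[1] - 1), 1e-7)
})

test_that("profiles survive a TSV + JSON round trip", {
  set.seed(7)
  gs <- genome_spec(c("c1", "c2"), c(400, 300))
  pos <- list(c1 = list(forward = sample(0:399, 30), reverse = sample(0:399, 30)),
              c2 = list(forward = sample(0:299, 20), reverse = sample(0:299, 20)))
  d <- binary_density(pos, gs, 20)
  p <- ncc_profile(d, shifts = 0:40)
  path <- tempfile(fileext = ".tsv")
  write_profile(p, path)
  p2 <- read_profile(path)
  expect_equal(p2$r, p$r, tolerance = 1e-12)
  expect_equal(p2$merged, p$merged, tolerance = 1e-12)
  expect_identical(p2$mode, p$mode)
  expect_identical(p2$genome$lengths, p$genome$lengths)
})
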