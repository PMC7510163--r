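#' @title Simulating read densities under the generative model
#' @name simulator
#' @description
#' The simulator produces data exactly under the read-density model: n
#' binding sites, each with a forward enriched region of width w and a
#' reverse enriched region w bp wide starting d bp downstream; signal read
#' 5' ends uniform over the enriched regions, noise 5' ends uniform over
#' the chromosome. The fixture defaults w = 100, d = 200, R = 50 match the
#' simulation constants used throughout the package's validation.
NULL

# Largest-remainder apportionment of `total` into parts proportional to
# `weights` (deterministic, sums exactly to `total`).
apportion <- function(total, weights) {
  if (total == 0 || sum(weights) == 0) return(rep(0, length(weights)))
  raw <- total * weights / sum(weights)
  base <- floor(raw)
  short <- round(total - sum(base))
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Place binding sites on a genome
#'
#' Sites are placed by seeded rejection sampling: anchors are drawn
#' uniformly, and a draw is kept only if its full footprint of 2w + d bp
#' lies in bounds and is disjoint from every accepted footprint. Sites are
#' apportioned to chromosomes proportionally to length (largest-remainder
#' rounding). For each anchor a, the forward enriched region is
#' \[a, a + w) and the reverse region's 5'-end coordinates span
#' \[a + d + w, a + d + 2w), so matching forward/reverse 5' ends are
#' exactly d + w apart.
#'
#' @param genome A [genome_spec()].
#' @param n Number of binding events.
#' @param w Enriched-region width (bp).
#' @param d Gap between the paired regions (bp).
#' @param seed Optional integer seed (local RNG state).
#' @return An object of class `SiteLayout`: per-chromosome sorted anchor
#'   vectors plus the geometry (w, d) and the genome.
#' @export
simulate_sites <- function(genome, n, w, d, seed = NULL) {
  stopifnot(is_genome_spec(genome))
  n <- as.integer(n)
  if (n < 0) stop("'n' must be >= 0")
  fp <- 2 * w + d
  if (n * fp > 0.5 * genome$total)
    stop("site footprints would cover more than half the genome; reduce n")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  n_per <- apportion(n, genome$lengths)
  anchors <- vector("list", length(genome$names))
  names(anchors) <- genome$names
  for (k in seq_along(genome$names)) {
    L <- genome$lengths[[k]]
    nk <- n_per[k]
    if (nk > 0 && L < fp) stop("chromosome ", genome$names[k],
                               " too short for a site footprint")
    acc <- numeric(0)
    tries <- 0L
    max_tries <- 1000L * max(n, 1L)
    while (length(acc) < nk) {
      if (tries >= max_tries)
        stop("site placement failed after ", max_tries,
             " draws; reduce n or enlarge the genome")
      tries <- tries + 1L
      a <- floor(stats::runif(1, 0, L - fp + 1))
      if (!length(acc) || all(abs(acc - a) >= fp)) acc <- c(acc, a)
    }
    anchors[[k]] <- sort(acc)
  }
  structure(list(anchors = anchors, w = w, d = d, genome = genome, n = n),
            class = "SiteLayout")
}

#' @export
print.SiteLayout <- function(x, ...) {
  cat("SiteLayout:", x$n, "site(s), w =", x$w, "bp, d =", x$d, "bp\n")
  invisible(x)
}

#' Enriched-region intervals of a layout
#'
#' @param layout A [simulate_sites()] result.
#' @return List per chromosome with matrices `E_f` and `E_g` (columns
#'   start, end; 0-based half-open). `E_g` spans the reverse-read 5'-end
#'   coordinates.
#' @export
site_regions <- function(layout) {
  lapply(layout$anchors, function(a) {
    list(E_f = cbind(start = a, end = a + layout$w),
         E_g = cbind(start = a + layout$d + layout$w,
                     end = a + layout$d + 2 * layout$w))
  })
}

# Sample `count` positions from an index space of `size` slots. Unsaturated
# counts (count <= size) are drawn without replacement - the model's
# unsaturated case assumes unique mapped positions - and saturated counts
# with replacement (duplicates then collapse in the density).
sample_slots <- function(size, count) {
  if (count == 0) return(numeric(0))
  if (count <= size) sample.int(size, count)
  else sample.int(size, count, replace = TRUE)
}

#' Draw reads under the model and binarise them
#'
#' Per strand, `round(M * alpha / 2)` signal 5' positions are drawn
#' uniformly over the enriched regions and `round(M * (1 - alpha) / 2)`
#' noise positions uniformly over the chromosome (restricted to placements
#' admitting a full-length read; overhanging reads are rejected at
#' simulation time). With `allocation = "deterministic"` these counts are
#' exact; `"multinomial"` draws the signal/noise split binomially per
#' strand. Duplicated positions collapse in the returned density and the
#' deduplicated total M_u is available via [dedup_count()].
#'
#' @param layout A [simulate_sites()] result.
#' @param params A [model_params()] consistent with the layout (same n, w,
#'   d and G).
#' @param seed Optional integer seed (local RNG state).
#' @param allocation `"deterministic"` (default) or `"multinomial"`.
#' @param keep_reads Also return the pre-collapse read list (for
#'   [write_alignments()]).
#' @return A [binary_density()]; with `keep_reads = TRUE`, a list with
#'   elements `density` and `reads`.
#' @export
simulate_reads <- function(layout, params, seed = NULL,
                           allocation = c("deterministic", "multinomial"),
                           keep_reads = FALSE) {
  allocation <- match.arg(allocation)
  stopifnot(inherits(layout, "SiteLayout"), inherits(params, "ModelParams"))
  if (params$n != layout$n || params$w != layout$w || params$d != layout$d ||
      params$G != layout$genome$total)
    stop("'params' (n, w, d, G) do not match the site layout")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  genome <- layout$genome
  w <- layout$w; d <- layout$d; R <- params$R
  per_strand <- round(params$M / 2)
  counts <- lapply(c(forward = 1, reverse = 2), function(.) {
    if (allocation == "deterministic") {
      sig <- round(params$M * params$alpha / 2)
    } else {
      sig <- stats::rbinom(1, per_strand, params$alpha)
    }
    c(signal = sig, noise = per_strand - sig)
  })
  if (params$alpha < 1 &&
      counts$forward[["noise"]] > genome$total - R + 1)
    stop("noise reads exceed available positions: M(1-alpha)/2 > G - R + 1")
  sites_per <- vapply(layout$anchors, length, 0L)
  pos <- vector("list", length(genome$names))
  names(pos) <- genome$names
  reads <- list()
  for (strand in c("forward", "reverse")) {
    sig_per <- apportion(counts[[strand]][["signal"]], sites_per * w)
    noise_per <- apportion(counts[[strand]][["noise"]],
                           pmax(genome$lengths - R + 1, 0))
    for (k in seq_along(genome$names)) {
      chrom <- genome$names[k]
      L <- genome$lengths[[k]]
      a <- layout$anchors[[k]]
      # signal: uniform over the strand's enriched regions
      idx <- sample_slots(length(a) * w, sig_per[k]) - 1
      site <- idx %/% w
      off <- idx %% w
      sig_pos <- if (strand == "forward") a[site + 1] + off
                 else a[site + 1] + d + w + off
      # noise: uniform over full-length placements on the chromosome
      noff <- sample_slots(L - R + 1, noise_per[k]) - 1
      noise_pos <- if (strand == "forward") noff else noff + R - 1
      pos[[chrom]][[strand]] <- c(sig_pos, noise_pos)
      if (keep_reads && (length(sig_pos) || length(noise_pos)))
        reads[[length(reads) + 1L]] <- data.frame(
          chrom = chrom, pos5 = c(sig_pos, noise_pos),
          strand = if (strand == "forward") "+" else "-")
    }
  }
  density <- binary_density(pos, genome, R)
  if (keep_reads) list(density = density, reads = do.call(rbind, reads))
  else density
}

#' Simulate a genome sequence with tunable repeat content
#'
#' Generates random sequence and oversows it with copies of a single random
#' repeat unit until roughly `repeat_fraction` of the genome is covered by
#' repeat copies. Exact mappability of the result ([compute_exact_mappability()])
#' has its unmappable positions concentrated in and around the repeat
#' copies, which makes the genome a controllable test bed for MSCC.
#'
#' @param lengths Named (or unnamed) vector of chromosome lengths.
#' @param repeat_fraction Target fraction of the genome covered by repeat
#'   copies, in \[0, 1\] (default 0).
#' @param repeat_unit_length Length of the repeated unit (default 25 bp).
#' @param seed Optional integer seed (local RNG state).
#' @return A [Biostrings::DNAStringSet].
#' @export
simulate_genome <- function(lengths, repeat_fraction = 0,
                            repeat_unit_length = 25, seed = NULL) {
  if (repeat_fraction < 0 || repeat_fraction > 1)
    stop("'repeat_fraction' must lie in [0, 1]")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  if (is.null(names(lengths)))
    names(lengths) <- paste0("chr", seq_along(lengths))
  unit <- paste(sample(c("A", "C", "G", "T"), repeat_unit_length,
                       replace = TRUE), collapse = "")
  seqs <- vapply(lengths, function(L) {
    s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
               collapse = "")
    if (repeat_fraction > 0) {
      # copies occupy non-overlapping unit-length slots so that the covered
      # fraction is k * unit / L; repeat_fraction = 1 tiles the chromosome
      slots <- seq(1, L - repeat_unit_length + 1, by = repeat_unit_length)
      k <- min(round(repeat_fraction * L / repeat_unit_length), length(slots))
      if (k > 0) {
        starts <- sort(sample(slots, k))
        for (st in starts)
          substr(s, st, st + repeat_unit_length - 1) <- unit
      }
    }
    s
  }, "")
  Biostrings::DNAStringSet(stats::setNames(seqs, names(lengths)))
}

#' One-call simulation of a ChIP-seq experiment under the model
#'
#' Places sites, draws reads and returns the density together with the
#' layout; a convenience wrapper used by the validation scripts.
#'
#' @param params A [model_params()].
#' @param chromosomes Number of equally sized chromosomes to split G into
#'   (default 1; G must be divisible by it).
#' @param seed Optional integer seed; site placement and read drawing use
#'   `seed` and `seed + 1`.
#' @param ... Passed on to [simulate_reads()].
#' @return List with `layout`, `density` and `genome`.
#' @export
simulate_chipseq <- function(params, chromosomes = 1L, seed = NULL, ...) {
  stopifnot(inherits(params, "ModelParams"))
  L <- params$G / chromosomes
  if (L != floor(L)) stop("'G' must be divisible by 'chromosomes'")
  genome <- genome_spec(paste0("chr", seq_len(chromosomes)),
                        rep(L, chromosomes))
  layout <- simulate_sites(genome, params$n, params$w, params$d, seed = seed)
  density <- simulate_reads(layout, params,
                            seed = if (is.null(seed)) NULL else seed + 1L, ...)
  list(layout = layout, density = density, genome = genome)
}
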