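#' @title Strand cross-correlation profiles
#' @description
#' NCC is the Pearson correlation between the binarised forward density f
#' and the reverse density g shifted by x, evaluated over the overlap window
#' i in \[0, L - x). MSCC restricts the index set to doubly mappable
#' positions: `forward_mask[i] == 1` and `reverse_mask[i + x] == 1`.
#'
#' Two estimators are available for NCC. `"exact"` computes the
#' unapproximated windowed Pearson coefficient: means and variances are
#' taken per shift over the overlap window. `"global"` uses the genome-wide
#' mean mu = M_c / 2L and variance mu(1 - mu) of a chromosome with M_c set
#' bits, together with the shifted-AND count |D_x| (the number of positions
#' where both f(i) and g(i + x) are one); it is the approximate form under
#' which the theoretical results are derived.
#'
#' Coefficients computed from fewer than 4 contributing positions, or from
#' a zero-variance window, are undefined and reported as `NA`, never as 0.
#' @name crosscorr
NULL

# ---- |D_x| counting engines -------------------------------------------------

# Sparse engine: enumerate (f, g) pairs with g - f in [0, max_shift] from the
# sorted position sets, in bounded-memory chunks. Cost is proportional to the
# number of such pairs.
dx_counts_sparse <- function(fpos, gpos, max_shift, chunk = 2e7) {
  nb <- max_shift + 1L
  out <- numeric(nb)
  if (!length(fpos) || !length(gpos)) return(out)
  lo <- findInterval(fpos - 0.5, gpos) + 1L
  hi <- findInterval(fpos + max_shift + 0.5, gpos)
  cnt <- as.integer(hi - lo)  + 1L
  keep <- which(cnt > 0L)
  if (!length(keep)) return(out)
  blocks <- split(keep, ceiling(cumsum(as.numeric(cnt[keep])) / chunk))
  for (b in blocks) {
    idx <- sequence(cnt[b]) + rep(lo[b] - 1L, cnt[b])
    d <- gpos[idx] - rep(fpos[b], cnt[b])
    out <- out + tabulate(d + 1, nbins = nb)
  }
  out
}

# Dense engine: circular cross-correlation by FFT on zero-padded indicator
# vectors; exact after rounding since all counts are integers.
dx_counts_fft <- function(fpos, gpos, L, max_shift) {
  N <- stats::nextn(L + max_shift + 1, c(2, 3, 5))
  a <- numeric(N); a[fpos + 1] <- 1
  A <- stats::fft(a)
  a[] <- 0; a[gpos + 1] <- 1
  B <- stats::fft(a)
  cc <- stats::fft(Conj(A) * B, inverse = TRUE) / N
  round(Re(cc[seq_len(max_shift + 1L)]))
}

# Pick an engine from the expected pair count unless forced.
dx_counts <- function(fpos, gpos, L, max_shift, engine = "auto") {
  if (engine == "auto") {
    est_pairs <- length(fpos) * (length(gpos) / L) * (max_shift + 1)
    engine <- if (est_pairs > 5e7 && L > max_shift) "fft" else "sparse"
  }
  switch(engine,
         sparse = dx_counts_sparse(fpos, gpos, max_shift),
         fft = dx_counts_fft(fpos, gpos, L, max_shift),
         stop("unknown engine: ", engine))
}

# Windowed Pearson coefficient from sufficient statistics of binary vectors:
# window size N, set-bit counts Sf, Sg, and co-occurrence count D.
r_from_counts <- function(N, Sf, Sg, D) {
  N <- as.numeric(N); Sf <- as.numeric(Sf)
  Sg <- as.numeric(Sg); D <- as.numeric(D)
  v1 <- Sf * (1 - Sf / N)
  v2 <- Sg * (1 - Sg / N)
  r <- (D - Sf * Sg / N) / sqrt(v1 * v2)
  r[v1 <= 0 | v2 <= 0 | N < 4] <- NA_real_
  r
}

# ---- per-chromosome computation ---------------------------------------------

# mask_info: NULL (NCC), list(kind = "uniform", R) or
# list(kind = "dense", forward = <logical>, reverse = <logical>).
chrom_cc <- function(fpos, gpos, L, shifts, estimator = "exact",
                     mask_info = NULL, engine = "auto") {
  ns <- length(shifts)
  max_shift <- max(shifts)
  if (is.null(mask_info)) {
    D <- dx_counts(fpos, gpos, L, max_shift, engine)[shifts + 1L]
    N <- pmax(L - shifts, 0)
    Sf <- findInterval(L - 0.5 - shifts, fpos)
    Sg <- length(gpos) - findInterval(shifts - 0.5, gpos)
    if (estimator == "global") {
      mu <- (length(fpos) + length(gpos)) / (2 * L)
      sigma <- mu * (1 - mu)
      r <- if (sigma > 0) (D / N - mu^2) / sigma else rep(NA_real_, ns)
      r[N < 4] <- NA_real_
    } else {
      r <- r_from_counts(N, Sf, Sg, D)
    }
    return(list(r = r, count = N))
  }
  if (mask_info$kind == "uniform") {
    R <- mask_info$R
    lo <- pmax(0, R - 1 - shifts)
    hi <- pmin(L - R, L - 1 - shifts)
    N <- pmax(hi - lo + 1, 0)
    f2 <- fpos[fpos <= L - R]
    g2 <- gpos[gpos >= R - 1]
    D <- dx_counts(f2, g2, L, max_shift, engine)[shifts + 1L]
    Sf <- findInterval(hi + 0.5, f2) - findInterval(lo - 0.5, f2)
    Sg <- findInterval(hi + shifts + 0.5, g2) - findInterval(lo + shifts - 0.5, g2)
    return(list(r = r_from_counts(N, Sf, Sg, D), count = N))
  }
  # dense mask: direct per-shift evaluation over the doubly mappable set
  fm <- mask_info$forward
  rm_ <- mask_info$reverse
  fbit <- logical(L); fbit[fpos + 1] <- TRUE
  gbit <- logical(L); gbit[gpos + 1] <- TRUE
  r <- count <- numeric(ns)
  for (k in seq_len(ns)) {
    x <- shifts[k]
    n_ov <- L - x
    if (n_ov < 1) { r[k] <- NA_real_; count[k] <- 0; next }
    iw <- seq_len(n_ov)
    sel <- fm[iw] & rm_[iw + x]
    N1 <- sum(sel)
    count[k] <- N1
    if (N1 < 4) { r[k] <- NA_real_; next }
    fv <- fbit[iw] & sel
    gv <- gbit[iw + x] & sel
    r[k] <- r_from_counts(N1, sum(fv), sum(gv), sum(fv & gv))
  }
  list(r = r, count = count)
}

new_cc_profile <- function(shifts, r, counts, mode, estimator, read_length,
                           genome, n_reads) {
  structure(list(shifts = shifts, r = r, counts = counts, merged = NULL,
                 mode = mode, estimator = estimator,
                 read_length = read_length, genome = genome,
                 n_reads = n_reads),
            class = "CCProfile")
}

profile_skeleton <- function(density, shifts, mode, estimator, compute_chrom) {
  shifts <- as.integer(shifts)
  if (length(shifts) < 1L || any(shifts < 0) || is.unsorted(shifts, strictly = TRUE))
    stop("'shifts' must be a strictly increasing vector of non-negative integers")
  genome <- density$genome
  chroms <- genome$names
  r <- counts <- matrix(NA_real_, nrow = length(shifts), ncol = length(chroms),
                        dimnames = list(NULL, chroms))
  for (chrom in chroms) {
    res <- compute_chrom(chrom)
    r[, chrom] <- res$r
    counts[, chrom] <- res$count
  }
  new_cc_profile(shifts, r, counts, mode, estimator, density$read_length,
                 genome, density$counts)
}

#' Naive cross-correlation (NCC) profile
#'
#' @param density A [binary_density()] with reads on both strands of at
#'   least one chromosome.
#' @param shifts Integer vector of strand shifts (default `0:1000`, which
#'   covers typical fragment lengths plus the read-length phantom position).
#' @param estimator `"exact"` (windowed Pearson, the default) or `"global"`
#'   (genome-wide moments; the approximation used by the theory).
#' @param engine `"auto"` (default), `"sparse"` or `"fft"` for the |D_x|
#'   counting path; the two engines give identical integer counts.
#' @param merge If `TRUE` (default) fill the genome-wide merged coefficient
#'   via [merge_profiles()].
#' @return A `CCProfile`: per-chromosome coefficients and contributing
#'   position counts indexed by shift, plus the merged coefficient.
#' @examples
#' gs <- genome_spec("chr1", 2000)
#' d <- binary_density(list(chr1 = list(forward = c(10, 50, 90),
#'                                      reverse = c(110, 150, 190))),
#'                     gs, read_length = 20)
#' p <- ncc_profile(d, shifts = 0:200)
#' p$merged[which.max(p$merged)]
#' @export
ncc_profile <- function(density, shifts = 0:1000,
                        estimator = c("exact", "global"),
                        engine = "auto", merge = TRUE) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(density, "BinaryDensity"))
  if (all(density$counts[, "forward"] == 0) || all(density$counts[, "reverse"] == 0))
    stop("density must contain reads on both strands of at least one chromosome")
  p <- profile_skeleton(density, shifts, "NCC", estimator, function(chrom) {
    chrom_cc(density$positions[[chrom]]$forward,
             density$positions[[chrom]]$reverse,
             density$genome$lengths[[chrom]], as.integer(shifts),
             estimator = estimator, mask_info = NULL, engine = engine)
  })
  if (merge) p <- merge_profiles(p) else p
}

#' Mappability-sensitive cross-correlation (MSCC) profile
#'
#' Identical to [ncc_profile()] except that, at each shift x, the Pearson
#' coefficient is computed only over the doubly mappable index set
#' `{i : forward_mask(i) = 1 and reverse_mask(i + x) = 1}`, with means and
#' variances taken over that set (exact estimator). Restricting to doubly
#' mappable positions removes the read-length "phantom" peak.
#'
#' @inheritParams ncc_profile
#' @param mask A [mappability_mask()] or [flat_mappability()] whose read
#'   length matches the density's.
#' @return A `CCProfile` with `mode = "MSCC"`.
#' @export
mscc_profile <- function(density, mask, shifts = 0:1000, engine = "auto",
                         merge = TRUE) {
  stopifnot(inherits(density, "BinaryDensity"),
            inherits(mask, "MappabilityMask"))
  if (mask$read_length != density$read_length)
    stop("mask read length (", mask$read_length,
         ") does not match density read length (", density$read_length, ")")
  p <- profile_skeleton(density, shifts, "MSCC", "exact", function(chrom) {
    mi <- if (mask$kind == "uniform") {
      list(kind = "uniform", R = mask$read_length)
    } else {
      c(list(kind = "dense"), dense_masks(mask, chrom))
    }
    chrom_cc(density$positions[[chrom]]$forward,
             density$positions[[chrom]]$reverse,
             density$genome$lengths[[chrom]], as.integer(shifts),
             estimator = "exact", mask_info = mi, engine = engine)
  })
  if (merge) p <- merge_profiles(p) else p
}

#' Merge per-chromosome coefficients into a genome-wide profile
#'
#' Applies Fisher's r-to-z transformation to each chromosome's coefficient,
#' takes a weighted average of the z values and back-transforms. The default
#' weight is `max(count - 3, 1)` (the inverse variance of z for a Pearson
#' coefficient estimated from `count` observations); chromosome length can
#' be used instead. Chromosomes undefined at a shift are excluded from that
#' shift's average. Coefficients with |r| = 1 are clamped to 1 - 1e-8 before
#' the transform (with a warning) to keep z finite.
#'
#' @param profile A `CCProfile`.
#' @param weights `"count"` (default) or `"length"`.
#' @return The profile with its `merged` coefficient vector filled.
#' @export
merge_profiles <- function(profile, weights = c("count", "length")) {
  weights <- match.arg(weights)
  stopifnot(inherits(profile, "CCProfile"))
  r <- profile$r
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    warning("coefficients with |r| = 1 clamped to 1 - 1e-8 before Fisher transform")
    r[!is.na(r) & r >= 1] <- 1 - 1e-8
    r[!is.na(r) & r <= -1] <- -(1 - 1e-8)
  }
  z <- atanh(r)
  w <- if (weights == "count") {
    pmax(profile$counts - 3, 1)
  } else {
    matrix(rep(profile$genome$lengths[colnames(r)], each = nrow(r)),
           nrow = nrow(r))
  }
  w[is.na(z)] <- NA_real_
  num <- rowSums(w * z, na.rm = TRUE)
  den <- rowSums(w, na.rm = TRUE)
  merged <- tanh(num / den)
  merged[den == 0] <- NA_real_
  profile$merged <- merged
  profile$weights <- weights
  profile
}

#' @export
print.CCProfile <- function(x, ...) {
  cat(x$mode, " profile (", x$estimator, " estimator), shifts ",
      min(x$shifts), "..", max(x$shifts), ", ",
      ncol(x$r), " chromosome(s)", sep = "")
  if (!is.null(x$merged) && any(!is.na(x$merged))) {
    i <- which.max(x$merged)
    cat(sprintf("; merged max %.4g at shift %d", x$merged[i], x$shifts[i]))
  }
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.CCProfile <- function(x, ...) {
  df <- data.frame(shift = x$shifts)
  for (chrom in colnames(x$r)) {
    df[[paste0("r_", chrom)]] <- x$r[, chrom]
    df[[paste0("count_", chrom)]] <- x$counts[, chrom]
  }
  df$merged <- if (is.null(x$merged)) NA_real_ else x$merged
  df
}

#' Write / read a cross-correlation profile
#'
#' The profile is stored as a TSV (columns `shift`, per-chromosome `r_*` and
#' `count_*`, and `merged`) with a JSON metadata sidecar (`<path>.json`)
#' recording mode, estimator, read length and the genome specification.
#'
#' @param profile A `CCProfile`.
#' @param path TSV output path.
#' @return `write_profile`: `path`, invisibly. `read_profile`: a `CCProfile`.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- list(mode = profile$mode, estimator = profile$estimator,
               read_length = profile$read_length,
               weights = profile$weights,
               chromosomes = profile$genome$names,
               lengths = as.numeric(profile$genome$lengths),
               n_reads = as.data.frame(profile$n_reads))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  genome <- genome_spec(meta$chromosomes, meta$lengths)
  chroms <- genome$names
  r <- as.matrix(df[paste0("r_", chroms)])
  counts <- as.matrix(df[paste0("count_", chroms)])
  colnames(r) <- colnames(counts) <- chroms
  n_reads <- as.matrix(meta$n_reads)
  rownames(n_reads) <- chroms
  p <- new_cc_profile(as.integer(df$shift), r, counts, meta$mode,
                      meta$estimator, meta$read_length, genome, n_reads)
  p$merged <- df$merged
  p$weights <- meta$weights
  p
}
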