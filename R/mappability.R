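#' Mappability masks for MSCC
#'
#' A `MappabilityMask` holds, per chromosome, binary indicators of uniquely
#' mappable read placements for a given read length R: the forward mask is
#' indexed by the leftmost base of a forward read, the reverse mask by the
#' rightmost base (the 5' end) of a reverse read. A position is "doubly
#' mappable" at shift x when `forward[i] == 1` and `reverse[i + x] == 1`;
#' MSCC is the Pearson correlation restricted to those positions.
#'
#' Two representations exist: `"dense"` (explicit 0/1 vectors, used for
#' real tracks and small synthetic genomes) and `"uniform"` (every in-bounds
#' placement mappable, stored implicitly; used for ideal simulations where
#' materialising genome-length vectors would be wasteful).
#'
#' @param forward,reverse Named lists of logical vectors (one per chromosome,
#'   chromosome-length).
#' @param genome A [genome_spec()].
#' @param read_length Read length R the mask was computed for.
#' @return An object of class `MappabilityMask`.
#' @export
mappability_mask <- function(forward, reverse, genome, read_length) {
  stopifnot(is_genome_spec(genome))
  R <- as.integer(read_length)
  if (R < 1L) stop("'read_length' must be >= 1")
  for (chrom in genome$names) {
    L <- genome$lengths[[chrom]]
    f <- forward[[chrom]]; r <- reverse[[chrom]]
    if (is.null(f) || is.null(r) || length(f) != L || length(r) != L)
      stop("masks must cover chromosome ", chrom, " at full length")
    if (R > 1L && any(f[seq(max(L - R + 2L, 1L), L)]))
      stop("forward mask of ", chrom, " marks placements overhanging the end")
    forward[[chrom]] <- as.logical(f)
    reverse[[chrom]] <- as.logical(r)
  }
  structure(list(kind = "dense", forward = forward, reverse = reverse,
                 genome = genome, read_length = R),
            class = "MappabilityMask")
}

#' Uniform (fully mappable) mask
#'
#' Represents a genome in which every position admitting a full-length read
#' is uniquely mappable: `forward[i] = 1` for `i <= L - R` and
#' `reverse[j] = 1` for `j >= R - 1` (0-based). Stored implicitly.
#'
#' @inheritParams mappability_mask
#' @return A `MappabilityMask` with `kind = "uniform"`.
#' @export
flat_mappability <- function(genome, read_length) {
  stopifnot(is_genome_spec(genome))
  R <- as.integer(read_length)
  if (R < 1L) stop("'read_length' must be >= 1")
  if (R > min(genome$lengths)) stop("read length exceeds shortest chromosome")
  structure(list(kind = "uniform", genome = genome, read_length = R),
            class = "MappabilityMask")
}

#' @export
print.MappabilityMask <- function(x, ...) {
  cat("MappabilityMask (", x$kind, "), R = ", x$read_length, " bp, ",
      length(x$genome$names), " chromosome(s)\n", sep = "")
  if (x$kind == "dense") {
    frac <- sum(vapply(x$forward, sum, 0)) / x$genome$total
    cat(sprintf("  forward mappable fraction: %.3f\n", frac))
  }
  invisible(x)
}

# Materialise dense logical masks for one chromosome (used by the direct
# per-shift engine and by tests).
dense_masks <- function(mask, chrom) {
  L <- mask$genome$lengths[[chrom]]
  R <- mask$read_length
  if (mask$kind == "uniform") {
    f <- rep(TRUE, L); if (R > 1L) f[seq(L - R + 2L, L)] <- FALSE
    r <- rep(TRUE, L); if (R > 1L) r[seq_len(R - 1L)] <- FALSE
    list(forward = f, reverse = r)
  } else {
    list(forward = mask$forward[[chrom]], reverse = mask$reverse[[chrom]])
  }
}

#' Derive the reverse-strand mask from leftmost-base mappability
#'
#' Single-track mappability files (e.g. the ENCODE convention) score the
#' leftmost base of a read placement regardless of strand. A reverse read
#' whose 5' end is at position j occupies `[j - R + 1, j]`, so its
#' mappability equals the leftmost-base score at `j - R + 1`.
#'
#' @param forward_mask Logical vector of leftmost-base mappability.
#' @param read_length Read length R.
#' @return Logical vector: `reverse[j] = forward[j - R + 1]`, 0 where the
#'   placement would start before the chromosome.
#' @examples
#' derive_reverse_mask(c(TRUE, TRUE, TRUE, TRUE, TRUE), 3)
#' @export
derive_reverse_mask <- function(forward_mask, read_length) {
  R <- as.integer(read_length)
  if (R < 1L) stop("'read_length' must be >= 1")
  L <- length(forward_mask)
  out <- rep(FALSE, L)
  if (L >= R) out[R:L] <- forward_mask[seq_len(L - R + 1L)]
  out
}

#' Load and binarise a BigWig mappability track
#'
#' Positions with a track value of exactly 1 are uniquely mappable; any
#' value below 1 - including positions without a value - is set to 0. The
#' track is interpreted as leftmost-base mappability; the reverse mask is
#' obtained with [derive_reverse_mask()].
#'
#' @param path BigWig file.
#' @param genome A [genome_spec()]; every chromosome must be present in the
#'   track's sequence set.
#' @param read_length Read length R the track was generated for.
#' @return A dense `MappabilityMask`.
#' @export
load_mappability_bigwig <- function(path, genome, read_length) {
  stopifnot(is_genome_spec(genome))
  R <- as.integer(read_length)
  bw <- rtracklayer::BigWigFile(path)
  avail <- GenomeInfoDb::seqnames(rtracklayer::seqinfo(bw))
  missing <- setdiff(genome$names, avail)
  if (length(missing))
    stop("chromosomes absent from BigWig track: ", paste(missing, collapse = ", "))
  fwd <- rev <- vector("list", length(genome$names))
  names(fwd) <- names(rev) <- genome$names
  for (chrom in genome$names) {
    L <- genome$lengths[[chrom]]
    which_gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(1, L))
    cov <- rtracklayer::import(bw, which = which_gr, as = "NumericList")[[1L]]
    v <- as.numeric(cov)
    if (length(v) < L) v <- c(v, numeric(L - length(v)))
    f <- !is.na(v) & v >= 1
    if (R > 1L && L >= R) f[seq(L - R + 2L, L)] <- FALSE  # no full-length placement
    fwd[[chrom]] <- f
    rev[[chrom]] <- derive_reverse_mask(f, R)
  }
  mappability_mask(fwd, rev, genome, R)
}

#' Exact-match mappability of a (small synthetic) genome
#'
#' A forward placement at position i is uniquely mappable iff its R-mer
#' contains no N and occurs exactly once among all R-mers of the genome and
#' of its reverse complement; a reverse placement with 5' end j is uniquely
#' mappable iff the placement starting at `j - R + 1` is. This is exact-match
#' uniqueness, a stricter criterion than mismatch-tolerant mappability, and
#' is intended for synthetic genomes where it can be computed exhaustively.
#'
#' @param x FASTA path or [Biostrings::DNAStringSet].
#' @param read_length Read length R (must not exceed the shortest chromosome).
#' @return A dense `MappabilityMask`.
#' @export
compute_exact_mappability <- function(x, read_length) {
  if (is.character(x)) x <- Biostrings::readDNAStringSet(x)
  R <- as.integer(read_length)
  if (R < 1L) stop("'read_length' must be >= 1")
  genome <- genome_spec_from_fasta(x)
  if (R > min(genome$lengths)) stop("read length exceeds shortest chromosome")
  seqs <- as.character(x)
  rcs <- as.character(Biostrings::reverseComplement(x))
  kmers_of <- function(s) {
    n <- nchar(s) - R + 1L
    if (n < 1L) character(0) else substring(s, seq_len(n), seq_len(n) + R - 1L)
  }
  per_chrom <- lapply(seqs, kmers_of)
  all_kmers <- c(unlist(per_chrom, use.names = FALSE),
                 unlist(lapply(rcs, kmers_of), use.names = FALSE))
  occ <- table(all_kmers)
  fwd <- rev <- vector("list", length(genome$names))
  names(fwd) <- names(rev) <- genome$names
  for (k in seq_along(genome$names)) {
    chrom <- genome$names[k]
    L <- genome$lengths[[chrom]]
    km <- per_chrom[[k]]
    uniq <- as.integer(occ[km]) == 1L & !grepl("N", km, fixed = TRUE)
    f <- c(uniq, rep(FALSE, R - 1L))[seq_len(L)]
    fwd[[chrom]] <- f
    rev[[chrom]] <- derive_reverse_mask(f, R)
  }
  mappability_mask(fwd, rev, genome, R)
}
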