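#' Binarised strand-specific read-start density
#'
#' The central data structure of the package: for each chromosome and strand,
#' the set of genomic positions (0-based) carrying at least one read 5' end.
#' Forward reads are represented by their leftmost base; reverse reads by
#' their rightmost base (the 5' end of the read on the reverse strand, i.e.
#' `b + R - 1` for a read whose leftmost base is `b`). Duplicate positions
#' collapse to a single set bit, which subsumes PCR-duplicate removal.
#'
#' @param positions Named list (one element per chromosome) of lists with
#'   integer vectors `forward` and `reverse` of 0-based 5'-end positions.
#' @param genome A [genome_spec()].
#' @param read_length Read length R in bp.
#' @return An object of class `BinaryDensity`: list with `positions` (sorted,
#'   unique, per chromosome/strand), `genome`, `read_length` and `counts`
#'   (set-bit totals per chromosome and strand). The deduplicated read total
#'   M_u equals `sum(counts)`.
#' @export
binary_density <- function(positions, genome, read_length) {
  stopifnot(is_genome_spec(genome))
  read_length <- as.integer(read_length)
  if (is.na(read_length) || read_length < 1L) stop("'read_length' must be >= 1")
  if (is.null(names(positions)) || !all(names(positions) %in% genome$names))
    stop("'positions' must be a named list over chromosomes of 'genome'")
  out <- vector("list", length(genome$names))
  names(out) <- genome$names
  counts <- matrix(0, nrow = length(genome$names), ncol = 2,
                   dimnames = list(genome$names, c("forward", "reverse")))
  for (chrom in genome$names) {
    L <- genome$lengths[[chrom]]
    p <- positions[[chrom]]
    fwd <- sort(unique(as.numeric(if (is.null(p)) numeric(0) else p$forward)))
    rev <- sort(unique(as.numeric(if (is.null(p)) numeric(0) else p$reverse)))
    if (length(fwd) && (fwd[1L] < 0 || fwd[length(fwd)] >= L))
      stop("forward positions out of range for ", chrom)
    if (length(rev) && (rev[1L] < 0 || rev[length(rev)] >= L))
      stop("reverse positions out of range for ", chrom)
    out[[chrom]] <- list(forward = fwd, reverse = rev)
    counts[chrom, ] <- c(length(fwd), length(rev))
  }
  structure(list(positions = out, genome = genome,
                 read_length = read_length, counts = counts),
            class = "BinaryDensity")
}

#' @export
print.BinaryDensity <- function(x, ...) {
  cat("BinaryDensity: R =", x$read_length, "bp,",
      length(x$genome$names), "chromosome(s)\n")
  cat("  set bits: forward", sum(x$counts[, "forward"]),
      "/ reverse", sum(x$counts[, "reverse"]),
      "(M_u =", sum(x$counts), ")\n")
  invisible(x)
}

#' Deduplicated mapped-read count M_u of a density
#' @param density A [binary_density()].
#' @return Total number of set bits over both strands and all chromosomes.
#' @export
dedup_count <- function(density) sum(density$counts)

# Modal value of an integer vector; ties resolved toward the smallest value.
modal_length <- function(x) {
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])
}

#' Read aligned reads into a binarised strand density
#'
#' Accepts BAM, SAM (converted on the fly) or 6-column BED. Forward reads
#' contribute their leftmost 0-based coordinate; reverse reads contribute
#' their rightmost aligned base (`b + R - 1`). Unmapped reads, reads below
#' `mapq_min` and reads on chromosomes absent from `genome` are skipped.
#' The SAM duplicate flag is ignored: binarisation subsumes deduplication.
#'
#' @param path Path to a `.bam`, `.sam` or `.bed` file.
#' @param genome A [genome_spec()]; chromosome names must resolve against it.
#' @param mapq_min Minimum mapping quality (default 0, i.e. no filtering;
#'   records without a MAPQ value are kept at the default).
#' @param read_length_override Optional read length R to use instead of the
#'   mode of the observed aligned lengths.
#' @return A [binary_density()].
#' @export
read_alignments <- function(path, genome, mapq_min = 0L,
                            read_length_override = NULL) {
  stopifnot(is_genome_spec(genome))
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  rec <- switch(ext,
    bam = read_alignments_bam(path),
    sam = read_alignments_bam(sam_to_bam(path)),
    bed = read_alignments_bed(path),
    stop("unsupported alignment format '.", ext, "' (use BAM, SAM or BED)"))
  mapq_ok <- rec$mapq >= mapq_min
  mapq_ok[is.na(mapq_ok)] <- mapq_min <= 0L  # no MAPQ: passes only if unfiltered
  keep <- mapq_ok & rec$chrom %in% genome$names
  rec <- lapply(rec, `[`, keep)
  if (length(rec$chrom) == 0L) stop("zero usable reads in ", path)
  if (is.null(read_length_override)) {
    R <- modal_length(rec$width)
    if (length(unique(rec$width)) > 1L)
      warning("inconsistent read lengths; using modal length R = ", R)
  } else {
    R <- as.integer(read_length_override)
  }
  pos <- lapply(split(seq_along(rec$chrom), rec$chrom), function(i) {
    fwd <- rec$start0[i][rec$strand[i] == "+"]
    rev5 <- rec$end0[i][rec$strand[i] == "-"]
    list(forward = fwd, reverse = rev5)
  })
  binary_density(pos, genome, R)
}

sam_to_bam <- function(path) {
  out <- tempfile(fileext = "")
  Rsamtools::asBam(path, destination = out, overwrite = TRUE,
                   indexDestination = FALSE)
}

read_alignments_bam <- function(path) {
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE),
    what = "mapq")
  ga <- as.data.frame(GenomicAlignments::readGAlignments(path, param = param))
  # SAM stores 255 for "MAPQ unavailable"
  mapq <- ga$mapq
  mapq[!is.na(mapq) & mapq == 255L] <- NA_real_
  list(chrom = as.character(ga$seqnames),
       start0 = ga$start - 1L,
       end0 = ga$end - 1L,
       width = ga$width,
       strand = as.character(ga$strand),
       mapq = mapq)
}

read_alignments_bed <- function(path) {
  gr <- as.data.frame(rtracklayer::import(path, format = "BED"))
  strand <- as.character(gr$strand)
  if (any(strand == "*"))
    stop("BED input must carry strand in column 6 for every record")
  list(chrom = as.character(gr$seqnames),
       start0 = gr$start - 1L,
       end0 = gr$end - 1L,
       width = gr$width,
       strand = strand,
       mapq = if (is.null(gr$score)) rep(NA_real_, nrow(gr)) else as.numeric(gr$score))
}

#' Write a binarised density (or read list) as SAM or BED alignments
#'
#' The inverse of [read_alignments()]: every 5'-end position becomes one
#' full-length, match-only alignment of length R. Positions whose read would
#' overhang the chromosome end are rejected with an error, so a written file
#' always round-trips to the identical density.
#'
#' @param x A [binary_density()], or a data.frame with columns `chrom`,
#'   `pos5` (0-based 5'-end coordinate) and `strand` (`"+"`/`"-"`), as
#'   returned by [simulate_reads()] with `keep_reads = TRUE`.
#' @param path Output file path.
#' @param format `"SAM"` or `"BED"`.
#' @param genome Genome (required when `x` is a data.frame).
#' @param read_length Read length (required when `x` is a data.frame).
#' @return `path`, invisibly.
#' @export
write_alignments <- function(x, path, format = c("SAM", "BED"),
                             genome = NULL, read_length = NULL) {
  format <- match.arg(format)
  if (inherits(x, "BinaryDensity")) {
    genome <- x$genome
    read_length <- x$read_length
    reads <- do.call(rbind, lapply(genome$names, function(chrom) {
      p <- x$positions[[chrom]]
      data.frame(
        chrom = rep(chrom, length(p$forward) + length(p$reverse)),
        pos5 = c(p$forward, p$reverse),
        strand = rep(c("+", "-"), c(length(p$forward), length(p$reverse))))
    }))
  } else {
    if (is.null(genome) || is.null(read_length))
      stop("'genome' and 'read_length' are required for a read list")
    reads <- as.data.frame(x)
  }
  stopifnot(is_genome_spec(genome), all(c("chrom", "pos5", "strand") %in% names(reads)))
  R <- as.integer(read_length)
  L <- genome$lengths[reads$chrom]
  start0 <- ifelse(reads$strand == "+", reads$pos5, reads$pos5 - R + 1)
  end0 <- start0 + R - 1
  if (nrow(reads) && (any(start0 < 0) || any(end0 >= L)))
    stop("refusing to write clipped reads: ", sum(start0 < 0 | end0 >= L),
         " position(s) do not admit a full-length read of R = ", R, " bp")
  if (format == "SAM") {
    header <- c("@HD\tVN:1.6\tSO:unknown",
                sprintf("@SQ\tSN:%s\tLN:%d", genome$names,
                        as.integer(genome$lengths)))
    body <- if (nrow(reads)) {
      ord <- order(match(reads$chrom, genome$names), start0)
      sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*",
              sprintf("read%08d", seq_len(nrow(reads))),
              ifelse(reads$strand[ord] == "-", 16L, 0L),
              reads$chrom[ord], as.integer(start0[ord]) + 1L, 60L, R)
    } else character(0)
    writeLines(c(header, body), path)
  } else {
    gr <- GenomicRanges::GRanges(
      seqnames = reads$chrom,
      ranges = IRanges::IRanges(start = start0 + 1, end = end0 + 1),
      strand = reads$strand,
      seqlengths = stats::setNames(as.integer(genome$lengths), genome$names))
    names(gr) <- sprintf("read%08d", seq_along(gr))
    S4Vectors::mcols(gr)$score <- rep(60L, length(gr))
    rtracklayer::export(gr, path, format = "BED")
  }
  invisible(path)
}
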