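#' Genome specification
#'
#' A minimal description of a genome as an ordered set of named chromosomes
#' with lengths. All coordinates used internally by the package are 0-based
#' half-open; conversion to the 1-based conventions of SAM/BED happens only
#' at the I/O boundary.
#'
#' @param names Character vector of unique chromosome names.
#' @param lengths Integer vector of chromosome lengths in bp (all >= 1).
#' @return An object of class `GenomeSpec`: a list with elements `names`,
#'   `lengths` (named) and `total` (the summed genome length G).
#' @examples
#' gs <- genome_spec(c("chr1", "chr2"), c(10000, 5000))
#' gs$total
#' @export
genome_spec <- function(names, lengths) {
  names <- as.character(names)
  lengths <- as.numeric(lengths)
  if (length(names) != length(lengths) || length(names) == 0L)
    stop("'names' and 'lengths' must be non-empty and of equal length")
  if (anyDuplicated(names))
    stop("chromosome names must be unique")
  if (any(!is.finite(lengths)) || any(lengths < 1) || any(lengths != floor(lengths)))
    stop("chromosome lengths must be positive integers")
  lengths <- stats::setNames(lengths, names)
  structure(list(names = names, lengths = lengths, total = sum(lengths)),
            class = "GenomeSpec")
}

#' @export
print.GenomeSpec <- function(x, ...) {
  cat("GenomeSpec:", length(x$names), "chromosome(s), G =",
      format(x$total, big.mark = ","), "bp\n")
  n <- min(length(x$names), 6L)
  for (i in seq_len(n))
    cat(sprintf("  %-12s %s bp\n", x$names[i], format(x$lengths[i], big.mark = ",")))
  if (length(x$names) > n) cat("  ...\n")
  invisible(x)
}

is_genome_spec <- function(x) inherits(x, "GenomeSpec")

#' Genome specification from a FASTA file or DNAStringSet
#'
#' @param x Path to a FASTA file, or a [Biostrings::DNAStringSet].
#' @return A [genome_spec()] with the sequence names and widths.
#' @export
genome_spec_from_fasta <- function(x) {
  if (is.character(x)) x <- Biostrings::readDNAStringSet(x)
  genome_spec(names(x), Biostrings::width(x))
}
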