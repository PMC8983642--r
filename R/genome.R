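#' Genome sequence I/O
#'
#' Genomes are held as a named `Biostrings::DNAStringSet` (uppercase
#' A/C/G/T/N). Sequence names are truncated at the first whitespace.
#'
#' @param path FASTA file path (multi-record, wrapped lines allowed).
#' @return A `DNAStringSet`.
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' @rdname read_genome_fasta
#' @param genome a named `DNAStringSet`.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, filepath = path, width = 70L)
  invisible(path)
}

#' Chromosome lengths of a genome
#' @param genome a named `DNAStringSet`.
#' @return Named integer vector of lengths in bp.
#' @export
genome_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

## Extract the sequence of a 0-based half-open region as a character string.
region_sequence <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) {
    stop(sprintf("chromosome '%s' not in genome", chrom), call. = FALSE)
  }
  len <- length(genome[[chrom]])  # XString length in bp
  if (start < 0 || end > len) {
    stop(sprintf("region %s:%d-%d outside chromosome bounds (length %d)",
                 chrom, start, end, len), call. = FALSE)
  }
  as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end))
}

#' Reverse complement of a DNA string
#' @param x a character scalar over A/C/G/T/N.
#' @return The reverse complement as a character scalar.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
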