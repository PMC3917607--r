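DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# reference container: a named DNA string --------------------------------

#' Create or coerce a reference sequence
#'
#' A reference is a single forward-strand DNA sequence with 1-based,
#' inclusive coordinates.
#'
#' @param sequence A DNA string (single character scalar) or an existing
#'   `dna_reference`.
#' @param name Sequence name used in FASTA/SAM/VCF output.
#' @return A `dna_reference` object with fields `name`, `sequence`, `length`.
#' @export
as_reference <- function(sequence, name = "ref") {
  if (inherits(sequence, "dna_reference")) return(sequence)
  stopifnot(is.character(sequence), length(sequence) == 1)
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence)) {
    abort("reference may only contain A, C, G, T")
  }
  structure(
    list(name = name, sequence = sequence, length = nchar(sequence)),
    class = "dna_reference"
  )
}

#' @export
print.dna_reference <- function(x, ...) {
  cat(sprintf("<dna_reference> %s: %s bp\n", x$name,
              format(x$length, big.mark = ",")))
  invisible(x)
}

ref_seq <- function(ref) as_reference(ref)$sequence
ref_len <- function(ref) as_reference(ref)$length

# substring of the reference, 1-based inclusive, clipped to bounds
ref_slice <- function(ref, from, to) {
  ref <- as_reference(ref)
  substr(ref$sequence, max(1L, from), min(ref$length, to))
}

# coerce reads input (character vector or tibble with seq column) to a tibble
as_read_tbl <- function(reads) {
  if (is.character(reads)) {
    return(tibble(read_id = paste0("read_", seq_along(reads)), seq = reads))
  }
  reads <- as_tibble(reads)
  if (!all(c("read_id", "seq") %in% names(reads))) {
    abort("reads must be a character vector or a tibble with columns read_id, seq")
  }
  reads
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# draw a derived RNG seed, kept within 32-bit integer range
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 97L * as.integer(offset)) %% 2147483587L
}

#' Average fold coverage of a read set
#'
#' @param n_reads Number of reads.
#' @param read_length Read length in bp.
#' @param ref_length Reference length in bp.
#' @return Average per-base fold coverage, `n_reads * read_length / ref_length`.
#' @examples
#' fold_coverage(76247, 28, 5386)
#' @export
fold_coverage <- function(n_reads, read_length, ref_length) {
  n_reads * read_length / ref_length
}
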