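# Plain-text I/O: FASTA, FASTQ, truth tables, track exports, VCF.

#' Write / read a reference as FASTA
#'
#' @param ref A [as_reference()] object.
#' @param path File path.
#' @return `read_reference_fasta()` returns a `dna_reference` (first record).
#' @export
write_reference_fasta <- function(ref, path) {
  ref <- as_reference(ref)
  x <- Biostrings::DNAStringSet(stats::setNames(ref$sequence, ref$name))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  as_reference(as.character(x[[1]]), name = names(x)[1])
}

#' Write / read reads as FASTQ
#'
#' Quality strings are a fixed placeholder: the simulator does not model base
#' qualities and no downstream step consumes them.
#'
#' @param reads Read tibble (columns `read_id`, `seq`) or character vector.
#' @param path File path.
#' @return `read_reads_fastq()` returns a tibble with `read_id`, `seq`.
#' @export
write_reads_fastq <- function(reads, path) {
  reads <- as_read_tbl(reads)
  x <- Biostrings::DNAStringSet(stats::setNames(reads$seq, reads$read_id))
  q <- Biostrings::BStringSet(strrep("I", nchar(reads$seq)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' @rdname write_reads_fastq
#' @export
read_reads_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(read_id = names(x), seq = unname(as.character(x)))
}

#' Write / read a spike truth table as TSV
#'
#' @param truth Truth tibble from [spike_indels()].
#' @param path File path.
#' @export
write_spike_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_truth
#' @export
read_spike_truth <- function(path) {
  as_tibble(read.delim(path, stringsAsFactors = FALSE))
}

#' Export a per-position track as TSV or bedGraph
#'
#' bedGraph output converts the package's 1-based inclusive positions to
#' 0-based half-open intervals.
#'
#' @param data A tibble containing a `pos` column.
#' @param value Name of the value column to export.
#' @param path File path.
#' @param track_name bedGraph track name.
#' @export
write_track_bedgraph <- function(data, value, path, track_name = value) {
  stopifnot("pos" %in% names(data), value %in% names(data))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s\"", track_name), con)
  chrom <- attr(data, "ref_name") %||% "ref"
  v <- data[[value]]
  keep <- !is.na(v)
  write.table(
    data.frame(chrom = chrom, start = data$pos[keep] - 1L,
               end = data$pos[keep], value = v[keep]),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' @rdname write_track_bedgraph
#' @export
write_track_tsv <- function(data, path) {
  write.table(data, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write confirmed indels as VCF or TSV
#'
#' Deletions are reported at the base before the deleted interval
#' (`POS = start - 1`, `REF` spans the deleted bases); insertions at their
#' reference anchor with the inserted bases appended to `ALT`. When the
#' inserted sequence is unknown a symbolic `<INS>` allele is written.
#'
#' @param confirmed Confirmed-indel tibble from [confirm_candidates()].
#' @param ref The reference.
#' @param path File path.
#' @export
write_indels_vcf <- function(confirmed, ref, path) {
  ref <- as_reference(ref)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", ref$name, ref$length),
    "##INFO=<ID=KIND,Number=1,Type=String,Description=\"Indel kind\">",
    "##INFO=<ID=SIZE,Number=1,Type=Integer,Description=\"Indel size in bp\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Reads sharing the gap\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  ), con)
  if (nrow(confirmed)) {
    confirmed <- arrange(confirmed, .data$position)
    for (i in seq_len(nrow(confirmed))) {
      r <- confirmed[i, ]
      if (r$kind == "deletion") {
        pos <- max(1L, r$ref_start - 1L)
        refa <- ref_slice(ref, pos, r$ref_end)
        alt <- substr(refa, 1L, 1L)
      } else {
        pos <- r$ref_start
        refa <- ref_slice(ref, pos, pos)
        alt <- if (is.na(r$bases)) "<INS>" else paste0(refa, r$bases)
      }
      writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tKIND=%s;SIZE=%d;SUPPORT=%d",
                         ref$name, pos, refa, alt, r$kind, r$size, r$support), con)
    }
  }
  invisible(path)
}
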