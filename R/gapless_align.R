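# Gapless k-mismatch alignment emulating the mismatch-only rapid aligners
# (ELAND/MAQ role) whose artifacts the detector consumes.

#' Align reads gaplessly with bounded mismatches
#'
#' Each read is placed at the gapless position (forward, then
#' reverse-complement) minimizing its mismatch count against the reference;
#' a read is unaligned if the minimum exceeds `max_mismatch`. Ties are broken
#' by smallest start, then forward strand. Reverse-strand hits are stored
#' reverse-complemented so all downstream data is forward-strand. The default
#' seed-and-extend search is an internal optimization whose results equal the
#' exhaustive scan over all `2 * (T - L + 1)` placements.
#'
#' @param reads Read tibble (columns `read_id`, `seq`) or character vector.
#' @param ref The reference.
#' @param max_mismatch Mismatch tolerance (default 2, the ELAND-era setting).
#' @param method `"seed"` (fast) or `"exhaustive"` (oracle).
#' @return A `read_alignments` object: list with `aligned` (tibble `read_id`,
#'   `start`, `end`, `strand`, `mismatches`, `seq_fwd`), `unaligned` (tibble
#'   `read_id`, `seq`; the pool fed to Smith-Waterman confirmation),
#'   `read_length`, `ref_name`, `ref_length`.
#' @export
align_reads <- function(reads, ref, max_mismatch = 2,
                        method = c("seed", "exhaustive")) {
  method <- match.arg(method)
  ref <- as_reference(ref)
  reads <- as_read_tbl(reads)
  stopifnot(max_mismatch >= 0)
  if (nrow(reads) == 0) {
    empty_aln <- tibble(read_id = character(), start = integer(),
                        end = integer(), strand = character(),
                        mismatches = integer(), seq_fwd = character())
    return(structure(list(aligned = empty_aln,
                          unaligned = tibble(read_id = character(), seq = character()),
                          read_length = NA_integer_, ref_name = ref$name,
                          ref_length = ref$length),
                     class = "read_alignments"))
  }
  if (any(nchar(reads$seq) > ref$length)) {
    abort("reads longer than the reference cannot be aligned")
  }
  hit <- cpp_align_reads(ref$sequence, reads$seq, as.integer(max_mismatch),
                         method == "exhaustive")
  ok <- !is.na(hit$start)
  aligned <- tibble(
    read_id = reads$read_id[ok],
    start = hit$start[ok],
    end = hit$start[ok] + nchar(reads$seq[ok]) - 1L,
    strand = hit$strand[ok],
    mismatches = hit$mismatches[ok],
    seq_fwd = hit$seq_fwd[ok]
  )
  structure(
    list(aligned = aligned,
         unaligned = tibble(read_id = reads$read_id[!ok], seq = reads$seq[!ok]),
         read_length = as.integer(round(median(nchar(reads$seq)))),
         ref_name = ref$name, ref_length = ref$length),
    class = "read_alignments"
  )
}

#' @rdname align_reads
#' @param read A single read sequence.
#' @return `align_read()` returns a one-row tibble (with `start = NA` when
#'   the read does not align).
#' @export
align_read <- function(read, ref, max_mismatch = 2,
                       method = c("seed", "exhaustive")) {
  stopifnot(length(read) == 1)
  aln <- align_reads(read, ref, max_mismatch, method)
  if (nrow(aln$aligned)) aln$aligned else
    tibble(read_id = aln$unaligned$read_id, start = NA_integer_,
           end = NA_integer_, strand = NA_character_,
           mismatches = NA_integer_, seq_fwd = NA_character_)
}

#' @export
print.read_alignments <- function(x, ...) {
  cat(sprintf("<read_alignments> vs %s (%s bp): %s aligned, %s unaligned\n",
              x$ref_name, format(x$ref_length, big.mark = ","),
              format(nrow(x$aligned), big.mark = ","),
              format(nrow(x$unaligned), big.mark = ",")))
  invisible(x)
}

# SAM text I/O ------------------------------------------------------------

#' Write / read gapless alignments as SAM
#'
#' Only gapless records (`<L>M` CIGARs) are accepted on input: the detector's
#' premise is mismatch-only alignment, and records with gapped CIGARs are
#' rejected with a diagnostic. Unaligned reads are stored with flag 4 and feed
#' the confirmation pool on re-import. The round trip is lossless for start,
#' strand and sequence.
#'
#' @param alignments A `read_alignments` object.
#' @param ref The reference (used for the header and to recompute mismatch
#'   counts on read-in).
#' @param path File path.
#' @export
write_sam <- function(alignments, ref, path) {
  stopifnot(inherits(alignments, "read_alignments"))
  ref <- as_reference(ref)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", ref$name, ref$length)), con)
  a <- alignments$aligned
  if (nrow(a)) {
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                       a$read_id, ifelse(a$strand == "-", 16L, 0L), ref$name,
                       a$start, nchar(a$seq_fwd), a$seq_fwd), con)
  }
  u <- alignments$unaligned
  if (nrow(u)) {
    writeLines(sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t*", u$read_id, u$seq),
               con)
  }
  invisible(path)
}

#' @rdname write_sam
#' @return `read_sam()` returns a `read_alignments` object.
#' @export
read_sam <- function(path, ref = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) < 10)
  if (length(bad)) {
    abort(sprintf("malformed SAM record at line %d", bad[1]))
  }
  flag <- as.integer(vapply(f, `[[`, "", 2))
  cigar <- vapply(f, `[[`, "", 6)
  seq <- toupper(vapply(f, `[[`, "", 10))
  id <- vapply(f, `[[`, "", 1)
  unmapped <- bitwAnd(flag, 4L) > 0L
  gapped <- !unmapped & !grepl("^[0-9]+M$", cigar)
  if (any(gapped)) {
    abort(sprintf(
      "record '%s' has gapped CIGAR '%s': this detector consumes mismatch-only alignments",
      id[which(gapped)[1]], cigar[which(gapped)[1]]))
  }
  start <- as.integer(vapply(f, `[[`, "", 4))
  strand <- ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")
  ref_name <- if (!is.null(ref)) as_reference(ref)$name else
    unique(vapply(f, `[[`, "", 3)[!unmapped])[1]
  mm <- rep(NA_integer_, length(id))
  if (!is.null(ref)) {
    ref <- as_reference(ref)
    k <- which(!unmapped)
    mm[k] <- vapply(k, function(i) {
      target <- substr(ref$sequence, start[i], start[i] + nchar(seq[i]) - 1L)
      sum(utf8ToInt(target) != utf8ToInt(seq[i]))
    }, integer(1))
  }
  aligned <- tibble(
    read_id = id[!unmapped], start = start[!unmapped],
    end = start[!unmapped] + nchar(seq[!unmapped]) - 1L,
    strand = strand[!unmapped], mismatches = mm[!unmapped],
    seq_fwd = seq[!unmapped]
  )
  unaligned_seq <- seq[unmapped]
  rev <- unmapped & bitwAnd(flag, 16L) > 0L
  if (any(rev)) unaligned_seq[bitwAnd(flag[unmapped], 16L) > 0L] <-
      revcomp(seq[rev])
  structure(
    list(aligned = aligned,
         unaligned = tibble(read_id = id[unmapped], seq = unaligned_seq),
         read_length = as.integer(round(median(nchar(seq)))),
         ref_name = ref_name %||% "ref",
         ref_length = if (!is.null(ref)) as_reference(ref)$length else NA_integer_),
    class = "read_alignments"
  )
}
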