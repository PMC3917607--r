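# Step 2: Smith-Waterman confirmation of candidate positions against the
# +/-40 bp reference segment, with shared-gap voting across the unaligned
# read pool; plus the faster flanking k-mer alternative.

#' Smith-Waterman confirmation parameters
#'
#' `gap_extend = 0` is essential: it prices a gap by its openings only, so a
#' 28 bp deletion costs no more than a 1 bp one and deletions up to the read
#' length can confirm. `gap_open` is set so that a gap must be anchored by
#' more than `|gap_open| / (2 * match)` matching bases on its short side
#' (8 bp at the defaults) -- long insertions leave too little read sequence
#' on either side of the inserted bases to meet this, so they are flagged by
#' step 1 but not SW-confirmed, while deletions keep the full read anchored.
#'
#' @param match Match score (default 2).
#' @param mismatch Mismatch score (default -3).
#' @param gap_open Gap opening score (default -16).
#' @param gap_extend Gap extension score (default 0).
#' @param segment_halfwidth Reference segment half-width around the candidate
#'   (default 40 bp).
#' @param proximity Maximum distance between the shared gap and the candidate
#'   position (default 5 bp, exclusive).
#' @param max_mismatches Maximum mismatches in a supporting alignment
#'   (default 1, the "fewer than two" rule).
#' @param min_support Minimum number of reads sharing the gap (default 5,
#'   i.e. more than M = 4).
#' @param prefilter_k Reads must share an exact k-mer with the segment to be
#'   SW-aligned at all (default 10); a cheap screen that bounds SW calls
#'   without discarding true supporters.
#' @return An `sw_params` list.
#' @export
sw_params <- function(match = 2, mismatch = -3, gap_open = -16, gap_extend = 0,
                      segment_halfwidth = 40, proximity = 5,
                      max_mismatches = 1, min_support = 5, prefilter_k = 10) {
  stopifnot(match > 0, mismatch < 0, gap_open <= 0, gap_extend <= 0,
            segment_halfwidth >= 10, proximity >= 1, max_mismatches >= 0,
            min_support >= 1, prefilter_k >= 4)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend,
                 segment_halfwidth = as.integer(segment_halfwidth),
                 proximity = proximity, max_mismatches = max_mismatches,
                 min_support = min_support,
                 prefilter_k = as.integer(prefilter_k)),
            class = "sw_params")
}

#' Smith-Waterman local alignment of a read against a segment
#'
#' Standard affine-gap local alignment. Among equal-scoring alignments the
#' traceback prefers ungapped continuation (fewest gap openings) and every
#' reported gap is shifted to its leftmost equivalent position, so identical
#' indels in different reads land on identical reference intervals.
#'
#' @param read Read sequence.
#' @param segment Reference segment.
#' @param params An [sw_params()].
#' @return An `sw_alignment` list: `score`, aligned spans (`seg_start`,
#'   `seg_end`, `read_start`, `read_end`), `n_mismatch`, `n_gaps`, a `gaps`
#'   tibble (kind, segment interval, read interval, size), and the gapped
#'   alignment strings.
#' @export
sw_align <- function(read, segment, params = sw_params()) {
  res <- cpp_sw_align(read, segment, params$match, params$mismatch,
                      params$gap_open, params$gap_extend)
  res$gaps <- as_tibble(res$gaps)
  structure(res, class = "sw_alignment")
}

#' @export
print.sw_alignment <- function(x, ...) {
  cat(sprintf("<sw_alignment> score %g, segment %d-%d, read %d-%d, %d mismatch(es), %d gap(s)\n",
              x$score, x$seg_start, x$seg_end, x$read_start, x$read_end,
              x$n_mismatch, x$n_gaps))
  if (nzchar(x$aligned_segment)) {
    cat(" seg: ", x$aligned_segment, "\n read:", x$aligned_read, "\n")
  }
  invisible(x)
}

#' Confirm a candidate indel position by shared-gap voting
#'
#' Extracts the reference segment `X[p - 40 .. p + 40]`, Smith-Waterman
#' aligns the pooled reads sharing an exact k-mer with it (in the
#' orientations that share one -- a supporting alignment always contains an
#' exact run of at least `prefilter_k` bases, so the screen cannot lose a
#' supporter), and counts a read as supporting a gap when its alignment has
#' exactly one gap, at most `params$max_mismatches` mismatches, and the gap
#' interval lies within `params$proximity` bp of `p` (interval distance: a
#' long deletion may be flagged from either boundary). The candidate is
#' confirmed when the modal gap interval is shared by at least
#' `params$min_support` reads; the confirmed position is the shared
#' interval's own left-normalized start, which may differ from the candidate.
#'
#' @param candidate Candidate position (1-based).
#' @param pool Unaligned read pool (tibble with `read_id`, `seq`, or a
#'   character vector) -- typically `alignments$unaligned`.
#' @param ref The reference.
#' @param params An [sw_params()].
#' @return A confirmed-indel tibble with zero or one row: `position`, `kind`,
#'   `size`, `support`, `ref_start`, `ref_end`, `bases`, `source_candidate`.
#' @export
confirm_candidate <- function(candidate, pool, ref, params = sw_params()) {
  ref <- as_reference(ref)
  pool <- as_read_tbl(pool)
  hw <- params$segment_halfwidth
  if (candidate < hw + 1 || candidate > ref$length - hw) {
    warn(sprintf("candidate %d is within %d bp of a reference end; cannot confirm",
                 candidate, hw))
    return(empty_confirmed())
  }
  rows <- confirm_scan(candidate, pool, ref, params)
  vote_shared_gap(rows, candidate, pool$seq, ref, params)
}

empty_confirmed <- function() {
  tibble(position = integer(), kind = character(), size = integer(),
         support = integer(), ref_start = integer(), ref_end = integer(),
         bases = character(), source_candidate = integer())
}

# SW-align the pool against each candidate segment (k-mer screened);
# one row per single-gap alignment
confirm_scan <- function(candidates, pool, ref, params) {
  as_tibble(cpp_confirm_scan(pool$seq, ref$sequence, as.integer(candidates),
                             params$segment_halfwidth, params$prefilter_k,
                             params$match, params$mismatch, params$gap_open,
                             params$gap_extend))
}

# shared-gap vote over the scan rows of one candidate
vote_shared_gap <- function(rows, candidate, pool_seqs, ref, params) {
  rows <- rows[rows$n_mismatch <= params$max_mismatches &
                 pmax(rows$ref_start - candidate,
                      candidate - rows$ref_end, 0) < params$proximity, ,
               drop = FALSE]
  if (!nrow(rows)) return(empty_confirmed())
  key <- paste(rows$kind, rows$ref_start, rows$ref_end, rows$size, sep = ":")
  tab <- sort(table(key), decreasing = TRUE)
  if (tab[1] < params$min_support) return(empty_confirmed())
  voters <- rows[key == names(tab)[1], , drop = FALSE]
  kind <- voters$kind[1]
  bases <- if (kind == "deletion") {
    substr(ref$sequence, voters$ref_start[1], voters$ref_end[1])
  } else {
    # inserted string: modal value across voters (a sequencing error next to
    # the insertion can distort any single read's gap content)
    oriented <- ifelse(voters$strand == "-",
                       revcomp(pool_seqs[voters$read_index]),
                       pool_seqs[voters$read_index])
    ins <- substr(oriented, voters$read_start, voters$read_end)
    names(sort(table(ins), decreasing = TRUE))[1]
  }
  tibble(position = voters$ref_start[1], kind = kind, size = voters$size[1],
         support = nrow(voters), ref_start = voters$ref_start[1],
         ref_end = voters$ref_end[1], bases = bases,
         source_candidate = as.integer(candidate))
}

#' Confirm a set of candidate positions
#'
#' Runs the shared-gap vote of [confirm_candidate()] over a candidate vector
#' (one batched alignment scan) and deduplicates confirmations of the same
#' indel reached from neighbouring candidates, keeping the best-supported
#' one.
#'
#' @param candidates Candidate positions (vector or [select_candidates()]
#'   output).
#' @inheritParams confirm_candidate
#' @return Confirmed-indel tibble (possibly empty).
#' @export
confirm_candidates <- function(candidates, pool, ref, params = sw_params()) {
  out <- confirm_candidates_raw(candidates, pool, ref, params)
  if (nrow(out)) {
    out <- out |>
      group_by(.data$kind, .data$ref_start, .data$ref_end) |>
      slice(which.max(.data$support)) |>
      ungroup() |>
      arrange(.data$position)
  }
  out
}

# per-candidate confirmations before interval deduplication (one row per
# candidate that confirmed)
confirm_candidates_raw <- function(candidates, pool, ref, params = sw_params()) {
  if (inherits(candidates, "candidate_set")) candidates <- candidates$pos
  ref <- as_reference(ref)
  pool <- as_read_tbl(pool)
  hw <- params$segment_halfwidth
  candidates <- candidates[candidates >= hw + 1 & candidates <= ref$length - hw]
  if (!length(candidates) || !nrow(pool)) return(empty_confirmed())
  rows <- confirm_scan(candidates, pool, ref, params)
  purrr::map(candidates, function(p) {
    vote_shared_gap(rows[rows$candidate == p, , drop = FALSE], p, pool$seq,
                    ref, params)
  }) |>
    bind_rows()
}

#' Flanking k-mer confirmation
#'
#' A faster, alignment-free alternative to Smith-Waterman confirmation: take
#' a k-mer just upstream and a k-mer just downstream of the candidate
#' position, find the reads containing both exactly once, and compare the
#' distance between the two k-mers in the read with their distance in the
#' reference. The shared difference is the signed indel size (positive
#' insertion, negative deletion); zero means no indel.
#'
#' Both flanks must lie outside the indel for carrier reads to contain them,
#' but the indel's extent is unknown a priori, so the flanks are scanned over
#' small offsets: the upstream k-mer ends at `p - u - 1` (u = 0..`proximity`,
#' absorbing candidate imprecision) and the downstream k-mer starts at
#' `p + d` (d = 0..`max_scan`, stepping over the deleted interval or the
#' inserted bases). The first offset pair at which a strict majority of the
#' informative reads agree on a nonzero difference is reported; the
#' difference itself does not depend on the offsets.
#'
#' @param candidate Candidate position (1-based).
#' @param reads Read tibble or character vector (all reads, aligned or not).
#' @param ref The reference.
#' @param k Flank length (default 6, minimum 4).
#' @param proximity Upstream scan range, matching the candidate imprecision
#'   tolerated by SW confirmation (default 5).
#' @param max_scan Downstream scan range, bounding the detectable deletion
#'   size (default 20).
#' @param min_informative Minimum reads containing both flanks for a vote to
#'   count (default 5).
#' @param flank_window Flank k-mers must be unique within this many bp of the
#'   candidate (default 200); non-unique flanks are skipped.
#' @return A one-row tibble: `candidate`, `delta` (signed size or `NA`),
#'   `n_informative`, `n_votes` (reads voting for `delta`).
#' @export
flank_kmer_confirm <- function(candidate, reads, ref, k = 6, proximity = 5,
                               max_scan = 20, min_informative = 5,
                               flank_window = 200) {
  stopifnot(k >= 4)
  ref <- as_reference(ref)
  reads <- as_read_tbl(reads)
  p <- as.integer(candidate)
  none <- tibble(candidate = p, delta = NA_integer_,
                 n_informative = 0L, n_votes = 0L)
  seqs <- c(reads$seq, revcomp(reads$seq))
  neighborhood <- ref_slice(ref, p - flank_window, p + flank_window)
  any_unique <- FALSE
  for (u in 0:proximity) {
    ua <- p - u - k
    if (ua < 1) break
    up <- substr(ref$sequence, ua, p - u - 1L)
    if (count_occurrences(neighborhood, up) != 1) next
    hits_up <- grepl(up, seqs, fixed = TRUE)
    if (!any(hits_up)) next
    for (d in 0:max_scan) {
      if (p + d + k - 1L > ref$length) break
      down <- substr(ref$sequence, p + d, p + d + k - 1L)
      if (count_occurrences(neighborhood, down) != 1) next
      any_unique <- TRUE
      ref_dist <- (p + d) - ua
      deltas <- integer(0)
      for (s in seqs[hits_up]) {
        iu <- gregexpr(up, s, fixed = TRUE)[[1]]
        id <- gregexpr(down, s, fixed = TRUE)[[1]]
        if (length(iu) == 1 && iu[1] > 0 && length(id) == 1 && id[1] > 0 &&
            id[1] > iu[1]) {
          deltas <- c(deltas, (id[1] - iu[1]) - ref_dist)
        }
      }
      if (length(deltas) < min_informative) next
      tab <- sort(table(deltas), decreasing = TRUE)
      winner <- as.integer(names(tab)[1])
      votes <- as.integer(tab[1])
      if (winner != 0 && votes > length(deltas) / 2) {
        return(tibble(candidate = p, delta = winner,
                      n_informative = length(deltas), n_votes = votes))
      }
    }
  }
  if (!any_unique) {
    warn("no unique flanking k-mers near the candidate; increase k")
  }
  none
}

count_occurrences <- function(x, pattern) {
  hits <- gregexpr(pattern, x, fixed = TRUE)[[1]]
  if (hits[1] == -1) 0L else length(hits)
}
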