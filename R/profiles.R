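# Per-position depth and mismatch tracks, local-median smoothing, and the
# normalized tracks that feed the indel detector.

coverage_from_footprints <- function(starts, ends, ref_length) {
  a <- pmax(starts, 1L)
  b <- pmin(ends, ref_length)
  keep <- b >= a
  if (!any(keep)) return(integer(ref_length))
  inc <- tabulate(a[keep], nbins = ref_length)
  dec <- tabulate(b[keep] + 1L, nbins = ref_length + 1L)[seq_len(ref_length)]
  cumsum(inc - dec)
}

#' Depth track on end-trimmed reads
#'
#' `depth` at position k counts aligned reads whose trimmed footprint
#' `[start + trim, start + L - 1 - trim]` covers k. Trimming the `trim` bp at
#' either read end removes the edge-effect alignments that keep raw coverage
#' above zero at an indel, so the trimmed depth drops to zero when an indel is
#' carried by all reads.
#'
#' @param alignments A `read_alignments` object.
#' @param trim Bases ignored at each read end (default 8; `2 * trim` must be
#'   smaller than the read length).
#' @return A tibble with `pos`, `depth` (trimmed) and `depth_untrimmed`.
#' @export
depth_track <- function(alignments, trim = 8) {
  stopifnot(inherits(alignments, "read_alignments"))
  a <- alignments$aligned
  T <- alignments$ref_length
  lens <- if (nrow(a)) nchar(a$seq_fwd) else integer()
  if (nrow(a) && any(2 * trim >= lens)) {
    abort("2 * trim must be smaller than the read length")
  }
  tibble(
    pos = seq_len(T),
    depth = coverage_from_footprints(a$start + trim, a$end - trim, T),
    depth_untrimmed = coverage_from_footprints(a$start, a$end, T)
  )
}

#' Mismatch tracks from untrimmed aligned reads
#'
#' For each reference position k, `m_a`..`m_t` count aligned read bases equal
#' to each letter; the mismatch vector is the 3 counts for the letters other
#' than the reference base, of which `m1` and `m2` are the largest and second
#' largest (ties among letters broken alphabetically). Mismatch counts use
#' untrimmed reads: trimming is applied only to the depth function.
#'
#' @param alignments A `read_alignments` object.
#' @param ref The reference.
#' @return A tibble with `pos`, `ref_base`, `m_a`, `m_c`, `m_g`, `m_t`,
#'   `m1`, `m2`.
#' @export
mismatch_tracks <- function(alignments, ref) {
  stopifnot(inherits(alignments, "read_alignments"))
  ref <- as_reference(ref)
  T <- ref$length
  a <- alignments$aligned
  counts <- cpp_pileup(T, a$start, a$seq_fwd)
  refi <- match(strsplit(ref$sequence, "")[[1]], DNA_BASES)
  mm <- matrix(as.numeric(counts), nrow = 4)
  mm[cbind(refi, seq_len(T))] <- -Inf
  m1 <- pmax(mm[1, ], mm[2, ], mm[3, ], mm[4, ])
  top <- max.col(t(mm), ties.method = "first")
  mm[cbind(top, seq_len(T))] <- -Inf
  m2 <- pmax(mm[1, ], mm[2, ], mm[3, ], mm[4, ])
  tibble(
    pos = seq_len(T), ref_base = DNA_BASES[refi],
    m_a = counts[1, ], m_c = counts[2, ], m_g = counts[3, ], m_t = counts[4, ],
    m1 = as.integer(m1), m2 = as.integer(m2)
  )
}

#' Local median smoothing
#'
#' Per-position median over the window `{j : |j - k| < half_width}`, clipped
#' at the sequence ends.
#'
#' @param x Numeric track.
#' @param half_width Window half-width in bp (>= 1).
#' @return Smoothed numeric vector of the same length.
#' @export
median_smooth <- function(x, half_width) {
  stopifnot(half_width >= 1)
  n <- length(x)
  if (n == 0) abort("cannot smooth an empty track")
  hw <- as.integer(half_width)
  w <- 2L * hw - 1L
  if (w >= n) {
    return(vapply(seq_len(n), function(k) {
      median(x[max(1L, k - hw + 1L):min(n, k + hw - 1L)])
    }, numeric(1)))
  }
  out <- stats::runmed(x, w, endrule = "keep")
  edge <- c(seq_len(hw - 1L), seq.int(n - hw + 2L, n))
  out[edge] <- vapply(edge, function(k) {
    median(x[max(1L, k - hw + 1L):min(n, k + hw - 1L)])
  }, numeric(1))
  as.numeric(out)
}

#' Position profiles: raw, smoothed and normalized tracks
#'
#' `position_profiles()` joins the depth and mismatch tracks;
#' `smooth_profiles()` adds the local-median references `d_bar` and `m1_bar`;
#' `normalize_profiles()` adds the normalized depth `d_hat = depth / d_bar`
#' and the gated normalized mismatch
#' `m1_hat = (m1 / m1_bar) * [m1 > 2 * m2]`, where the indicator requires the
#' top mismatch letter to be more than twice the runner-up (a sequencing-error
#' column spreads over all three letters; an indel edge concentrates on one).
#' `compute_profiles()` chains all three.
#'
#' Degenerate positions: where `d_bar = 0` the position is flagged
#' `uncovered` and `d_hat` set to 0 (such positions never become candidates);
#' `m1_bar` is floored at 1 so that a locally clean lane does not blow up the
#' mismatch ratio.
#'
#' @param alignments A `read_alignments` object.
#' @param ref The reference.
#' @param trim Read-end trim for the depth track (default 8).
#' @param w_d,w_m Median window half-widths for depth and mismatch; both must
#'   exceed `2 * read_length` (default `2L + 1`).
#' @return An `indel_profiles` tibble (one row per reference position).
#' @export
position_profiles <- function(alignments, ref, trim = 8) {
  ref <- as_reference(ref)
  out <- left_join(depth_track(alignments, trim = trim),
                   mismatch_tracks(alignments, ref), by = "pos")
  structure(out,
            class = c("indel_profiles", class(out)),
            read_length = alignments$read_length,
            trim = trim, ref_name = ref$name)
}

#' @rdname position_profiles
#' @param profiles An `indel_profiles` tibble.
#' @param read_length Read length L; defaults to the value recorded by
#'   [position_profiles()].
#' @export
smooth_profiles <- function(profiles, w_d = NULL, w_m = NULL,
                            read_length = NULL) {
  L <- read_length %||% attr(profiles, "read_length")
  if (is.null(L) || is.na(L)) abort("read_length unknown; pass it explicitly")
  w_d <- w_d %||% (2L * L + 1L)
  w_m <- w_m %||% (2L * L + 1L)
  if (w_d <= 2 * L || w_m <= 2 * L) {
    abort("w_d and w_m must be larger than 2 * read_length")
  }
  profiles$d_bar <- median_smooth(profiles$depth, w_d)
  profiles$m1_bar <- median_smooth(profiles$m1, w_m)
  attr(profiles, "w_d") <- w_d
  attr(profiles, "w_m") <- w_m
  profiles
}

#' @rdname position_profiles
#' @export
normalize_profiles <- function(profiles) {
  if (!"d_bar" %in% names(profiles)) abort("smooth the profiles first (smooth_profiles)")
  profiles$uncovered <- profiles$d_bar == 0
  profiles$d_hat <- ifelse(profiles$uncovered, 0, profiles$depth / pmax(profiles$d_bar, 1e-12))
  profiles$m1_hat <- (profiles$m1 / pmax(profiles$m1_bar, 1)) *
    (profiles$m1 > 2 * profiles$m2)
  profiles
}

#' @rdname position_profiles
#' @export
compute_profiles <- function(alignments, ref, trim = 8, w_d = NULL, w_m = NULL) {
  position_profiles(alignments, ref, trim = trim) |>
    smooth_profiles(w_d = w_d, w_m = w_m) |>
    normalize_profiles()
}
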