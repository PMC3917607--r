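# Step 1: the indel detector function f(k), candidate selection under a
# per-site cap, and the iterative thresholding loop.

#' Indel detector function
#'
#' `f(k)` is the window sum of the normalized gated mismatch track divided by
#' the normalized depth:
#' `f(k) = sum_{|j-k| <= w_f} m1_hat(j) / d_hat(k)`.
#' It rises at indel positions, where depth drops and edge mismatches
#' concentrate. The depth in the denominator is floored at one read's worth
#' (`d_hat >= 1 / d_bar`) so that trimmed-depth-zero positions -- the
#' strongest signal, produced by an indel carried by all reads -- rank
#' highest finite rather than dividing by zero. `f` is defined for
#' `k = w_f + 1 .. T - w_f`.
#'
#' @param profiles Normalized `indel_profiles` (see [compute_profiles()]).
#' @param w_f Summation half-width in bp (default 5, spanning the mismatch
#'   shoulder an aligner tolerance of ~2 produces at an indel edge).
#' @return A `detector_track` tibble with `pos`, `f`, `uncovered`.
#' @export
detector_track <- function(profiles, w_f = 5) {
  if (!"m1_hat" %in% names(profiles)) abort("profiles must be normalized (compute_profiles)")
  stopifnot(w_f >= 1)
  T <- nrow(profiles)
  if (T < 2 * w_f + 1) abort("reference shorter than 2 * w_f + 1")
  win <- as.numeric(stats::filter(profiles$m1_hat, rep(1, 2 * w_f + 1),
                                  sides = 2))
  denom <- pmax(profiles$d_hat, 1 / pmax(profiles$d_bar, 1))
  f <- win / denom
  keep <- (w_f + 1):(T - w_f)
  out <- tibble(pos = profiles$pos[keep], f = f[keep],
                uncovered = profiles$uncovered[keep])
  # within a read length of a reference end the depth ramp is structural
  # (no read extends beyond the end), which fakes a depth drop; no indel is
  # assayable there, so those positions never become candidates
  L <- attr(profiles, "read_length") %||% 0L
  out$edge <- out$pos <= L | out$pos > T - L
  out$f[out$uncovered | out$edge] <- 0
  structure(out, class = c("detector_track", class(out)),
            w_f = w_f, read_length = attr(profiles, "read_length"),
            ref_name = attr(profiles, "ref_name"))
}

# would adding `k` to `accepted` place more than `cap` candidates inside some
# window of `win` bp?
cluster_violation <- function(k, accepted, win, cap) {
  nearby <- accepted[abs(accepted - k) < win]
  if (length(nearby) < cap) return(FALSE)
  pts <- sort(c(nearby, k))
  for (s in pts) {
    if (s > k) break
    if (k <= s + win - 1 && sum(pts >= s & pts <= s + win - 1) > cap) {
      return(TRUE)
    }
  }
  FALSE
}

#' Select candidate indel positions
#'
#' Threshold mode returns all positions with `f > f_thresh`; top-n mode the
#' `n` highest-`f` positions. In both modes candidates are accepted greedily
#' in decreasing `f` (ties to the smaller position) under a per-site cap: no
#' window of `window` bp (default `2L`) may hold more than `per_site_cap`
#' candidates, so a single strong site cannot consume the whole budget.
#' Positions flagged uncovered, or with `f = 0`, are never selected.
#'
#' @param track A [detector_track()].
#' @param mode `"top_n"` or `"threshold"`.
#' @param n Candidate budget (top-n mode); `Inf` ranks every eligible
#'   position.
#' @param f_thresh Threshold (threshold mode).
#' @param per_site_cap Maximum candidates per `window` bp (default 8).
#' @param window Clustering window in bp (default `2 * read_length`).
#' @return A `candidate_set` tibble with `pos`, `f`, `rank`, carrying
#'   attribute `gamma`, the fraction of defined positions selected.
#' @export
select_candidates <- function(track, mode = c("top_n", "threshold"), n = 400,
                              f_thresh = NULL, per_site_cap = 8,
                              window = NULL) {
  mode <- match.arg(mode)
  window <- window %||% (2L * (attr(track, "read_length") %||% 28L))
  pool <- track[!track$uncovered & track$f > 0, c("pos", "f")]
  if (mode == "threshold") {
    if (is.null(f_thresh)) abort("threshold mode needs f_thresh")
    pool <- pool[pool$f > f_thresh, ]
    n <- Inf
  } else {
    stopifnot(n >= 1)
  }
  pool <- pool[order(-pool$f, pool$pos), ]
  accepted <- integer(0)
  acc_f <- numeric(0)
  for (i in seq_len(nrow(pool))) {
    if (length(accepted) >= n) break
    k <- pool$pos[i]
    if (!cluster_violation(k, accepted, window, per_site_cap)) {
      accepted <- c(accepted, k)
      acc_f <- c(acc_f, pool$f[i])
    }
  }
  out <- tibble(pos = accepted, f = acc_f, rank = seq_along(accepted))
  structure(out, class = c("candidate_set", class(out)),
            gamma = length(accepted) / nrow(track),
            window = window, per_site_cap = per_site_cap)
}

#' Iterative detection without a fixed threshold
#'
#' Rather than fixing `f_thresh`, rank all eligible positions by `f`, pass
#' them to confirmation in batches of `batch` (default 200), and stop after
#' the first batch in which nothing confirms.
#'
#' @param track A [detector_track()].
#' @param confirmer Function taking a vector of candidate positions and
#'   returning a confirmed-indel tibble (see [confirm_candidates()]).
#' @param batch Batch size N.
#' @param per_site_cap,window Passed to [select_candidates()].
#' @return A list with `confirmed` (deduplicated tibble), `n_batches`,
#'   `n_tested`.
#' @export
iterative_detection <- function(track, confirmer, batch = 200,
                                per_site_cap = 8, window = NULL) {
  stopifnot(batch >= 1)
  ranked <- select_candidates(track, "top_n", n = Inf,
                              per_site_cap = per_site_cap, window = window)
  confirmed <- list()
  n_batches <- 0L
  n_tested <- 0L
  while (n_tested < nrow(ranked)) {
    idx <- seq.int(n_tested + 1L, min(n_tested + batch, nrow(ranked)))
    n_tested <- n_tested + length(idx)
    n_batches <- n_batches + 1L
    hit <- confirmer(ranked$pos[idx])
    if (is.null(hit) || nrow(hit) == 0) break
    confirmed[[n_batches]] <- hit
  }
  confirmed <- bind_rows(confirmed)
  if (nrow(confirmed)) {
    confirmed <- confirmed |>
      group_by(.data$kind, .data$ref_start, .data$ref_end) |>
      slice(which.max(.data$support)) |>
      ungroup() |>
      arrange(.data$position)
  }
  list(confirmed = confirmed, n_batches = n_batches, n_tested = n_tested)
}
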