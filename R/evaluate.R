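# Scoring detection runs against spike truth, and the full
# sensitivity/specificity benchmark grid under candidate budgets.

#' Score a detection run against spike truth
#'
#' A truth record is a true positive when a confirmed indel lies within
#' `match_window` bp of it; each confirmed indel can match at most one truth
#' record (nearest wins), so clustered confirmations of one spike are not
#' double-counted. A confirmed indel is a false positive only when it lies
#' farther than `match_window` from every truth record: the evaluable
#' universe for specificity is the defined detector positions outside
#' `match_window` bp of any truth record, and redundant confirmations inside
#' a truth neighbourhood fall outside that universe. True negatives are the
#' evaluable positions not predicted, so `specificity = TN / (TN + FP)`.
#'
#' @param confirmed Confirmed-indel tibble.
#' @param truth Spike truth tibble.
#' @param track The [detector_track()] of the run (defines the evaluable
#'   positions), or an integer count of defined positions.
#' @param candidates Optional [select_candidates()] output; adds the
#'   candidate-stage columns.
#' @param match_window Matching window in bp (default 5).
#' @return A one-row tibble with counts (`n_true`, `n_candidates`,
#'   `tp_candidates`, `n_predictions`, `tp`, `fp`, `fn`, `tn`) and rates
#'   (`sensitivity`, `specificity`).
#' @export
score_run <- function(confirmed, truth, track, candidates = NULL,
                      match_window = 5) {
  n_true <- nrow(truth)
  if (inherits(track, "data.frame")) {
    defined <- track$pos
  } else {
    defined <- seq_len(as.integer(track))
  }
  near_truth <- rep(FALSE, length(defined))
  for (t in truth$position) {
    near_truth <- near_truth | abs(defined - t) <= match_window
  }
  n_evaluable <- sum(!near_truth)

  m <- match_predictions(confirmed$position, truth$position, match_window)
  tp <- sum(!is.na(m))
  near_any <- vapply(confirmed$position, function(p) {
    length(truth$position) > 0 && min(abs(truth$position - p)) <= match_window
  }, logical(1))
  fp <- sum(!near_any)
  fn <- n_true - tp
  tn <- n_evaluable - fp
  tp_cand <- NA_integer_
  n_cand <- NA_integer_
  if (!is.null(candidates)) {
    n_cand <- nrow(candidates)
    tp_cand <- sum(vapply(truth$position, function(t) {
      any(abs(candidates$pos - t) <= match_window)
    }, logical(1)))
  }
  tibble(
    n_true = n_true, n_candidates = n_cand, tp_candidates = tp_cand,
    n_predictions = nrow(confirmed),
    tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = if (n_true > 0) tp / n_true else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
  )
}

# nearest-wins one-to-one assignment of predictions to truth positions
match_predictions <- function(pred, truth, window) {
  m <- rep(NA_integer_, length(pred))
  if (!length(pred) || !length(truth)) return(m)
  pairs <- expand.grid(p = seq_along(pred), t = seq_along(truth))
  pairs$dist <- abs(pred[pairs$p] - truth[pairs$t])
  pairs <- pairs[pairs$dist <= window, , drop = FALSE]
  pairs <- pairs[order(pairs$dist, pairs$p), , drop = FALSE]
  used_t <- logical(length(truth))
  for (i in seq_len(nrow(pairs))) {
    p <- pairs$p[i]; t <- pairs$t[i]
    if (is.na(m[p]) && !used_t[t]) {
      m[p] <- t
      used_t[t] <- TRUE
    }
  }
  m
}

#' Run one spike-in condition through the full pipeline
#'
#' Simulates a lane from `config`, aligns, profiles, ranks candidates, and
#' confirms the top `max(budgets)` candidates; then scores the run at each
#' candidate budget (a budget's confirmations are those reached from its
#' top-ranked candidates, so scores are nested and non-decreasing in the
#' budget).
#'
#' @param config A [spike_config()].
#' @param budgets Candidate budgets to score (default `c(100, 200, 400)`).
#' @param sw [sw_params()] for confirmation.
#' @param trim,w_d,w_m,w_f,max_mismatch,per_site_cap Pipeline settings (see
#'   the profile and detector functions).
#' @param match_window Truth-matching window in bp.
#' @param keep_data Keep the simulated lane and intermediate objects in the
#'   result (default FALSE to save memory in grid runs).
#' @return A list with `scores` (tibble, one row per budget), `truth`, and,
#'   if `keep_data`, the lane, alignments, profiles, track, candidates and
#'   raw confirmations.
#' @export
benchmark_condition <- function(config, budgets = c(100, 200, 400),
                                sw = sw_params(), trim = 8, w_d = NULL,
                                w_m = NULL, w_f = 5, max_mismatch = 2,
                                per_site_cap = 8, match_window = 5,
                                keep_data = FALSE) {
  lane <- simulate_spiked_lane(config)
  aln <- align_reads(lane$reads, lane$ref, max_mismatch = max_mismatch)
  prof <- compute_profiles(aln, lane$ref, trim = trim, w_d = w_d, w_m = w_m)
  track <- detector_track(prof, w_f = w_f)
  cand <- select_candidates(track, "top_n", n = max(budgets),
                            per_site_cap = per_site_cap)
  raw <- confirm_candidates_raw(cand$pos, aln$unaligned, lane$ref, params = sw)
  if (nrow(raw)) {
    raw <- left_join(raw, cand |> select("pos", "rank") |>
                       rename(source_candidate = "pos"),
                     by = "source_candidate")
  } else {
    raw$rank <- integer()
  }
  scores <- purrr::map(sort(budgets), function(b) {
    cb <- cand[cand$rank <= b, ]
    conf <- raw[raw$rank <= b, , drop = FALSE]
    if (nrow(conf)) {
      conf <- conf |>
        group_by(.data$kind, .data$ref_start, .data$ref_end) |>
        slice(which.max(.data$support)) |>
        ungroup()
    }
    score_run(conf, lane$truth, track, candidates = cb,
              match_window = match_window) |>
      mutate(budget = b, .before = 1)
  }) |>
    bind_rows() |>
    mutate(kind = config$indel_kind, size = config$indel_size,
           fraction = config$spike_fraction, .before = 1)
  out <- list(scores = scores, truth = lane$truth)
  if (keep_data) {
    out <- c(out, list(lane = lane, alignments = aln, profiles = prof,
                       track = track, candidates = cand, confirmations = raw))
  }
  out
}

#' Sensitivity/specificity grid over kinds, sizes, fractions and budgets
#'
#' Runs the full spike-in -> align -> detect -> confirm -> score loop for
#' every combination and returns the benchmark grid (one row per condition
#' and budget).
#'
#' @param kinds Indel kinds to simulate.
#' @param sizes Indel sizes in bp.
#' @param fractions Spike fractions.
#' @param budgets Candidate budgets.
#' @param ref_length,n_reads,read_length,errors_per_read,spike_positions
#'   Lane geometry (defaults: the 5,386 bp reference, ~76k 28 bp reads with
#'   one error each, 50 spike positions at 100, 200, ..., 5000).
#' @param seed Integer seed; each condition uses a seed derived from it.
#' @param ... Passed to [benchmark_condition()].
#' @return The grid as a tibble.
#' @export
benchmark_grid <- function(kinds = c("insertion", "deletion"), sizes = 1:3,
                           fractions = c(1, 0.5, 0.25),
                           budgets = c(100, 200, 400), ref_length = 5386,
                           n_reads = 76000, read_length = 28,
                           errors_per_read = 1,
                           spike_positions = seq(100L, 5000L, by = 100L),
                           seed = 1, ...) {
  grid <- expand.grid(kind = kinds, size = sizes, fraction = fractions,
                      stringsAsFactors = FALSE)
  purrr::map(seq_len(nrow(grid)), function(i) {
    cfg <- spike_config(
      ref_length = ref_length, read_length = read_length, n_reads = n_reads,
      errors_per_read = errors_per_read, spike_positions = spike_positions,
      indel_size = grid$size[i], indel_kind = grid$kind[i],
      spike_fraction = grid$fraction[i], seed = derive_seed(seed, i)
    )
    benchmark_condition(cfg, budgets = budgets, ...)$scores
  }) |>
    bind_rows()
}
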