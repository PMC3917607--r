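# End-to-end orchestration: align -> profile -> detect -> confirm
# (-> genotype), with a run report.

#' Pipeline configuration
#'
#' Bundles all stage parameters with validated defaults. `w_d`/`w_m` default
#' to `2 * read_length + 1` (they must exceed `2L`); the candidate stage
#' either iterates batches of `batch` until a batch confirms nothing
#' (`mode = "iterative"`) or confirms a fixed `top_n` budget.
#'
#' @param read_length Read length L in bp.
#' @param max_mismatch Gapless aligner tolerance.
#' @param trim Read-end trim for the depth track.
#' @param w_d,w_m Median smoothing half-widths (`NULL` = `2L + 1`).
#' @param w_f Detector summation half-width.
#' @param sw [sw_params()] for confirmation.
#' @param mode `"iterative"` or `"top_n"`.
#' @param batch Iterative batch size N.
#' @param top_n Candidate budget for `mode = "top_n"`.
#' @param per_site_cap Candidates allowed per `2L` window.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(read_length = 28, max_mismatch = 2, trim = 8,
                            w_d = NULL, w_m = NULL, w_f = 5,
                            sw = sw_params(), mode = c("iterative", "top_n"),
                            batch = 200, top_n = 400, per_site_cap = 8) {
  mode <- match.arg(mode)
  L <- as.integer(read_length)
  w_d <- w_d %||% (2L * L + 1L)
  w_m <- w_m %||% (2L * L + 1L)
  if (w_d <= 2 * L || w_m <= 2 * L) abort("w_d and w_m must exceed 2 * read_length")
  if (2 * trim >= L) abort("2 * trim must be smaller than read_length")
  stopifnot(inherits(sw, "sw_params"), batch >= 1, top_n >= 1)
  structure(list(read_length = L, max_mismatch = max_mismatch, trim = trim,
                 w_d = w_d, w_m = w_m, w_f = w_f, sw = sw, mode = mode,
                 batch = batch, top_n = top_n, per_site_cap = per_site_cap),
            class = "pipeline_config")
}

#' Run the full two-step indel detection pipeline
#'
#' Stage order: gapless alignment (or an imported mismatch-only SAM), depth
#' and mismatch profiling, detector ranking, Smith-Waterman confirmation of
#' candidates against the unaligned pool.
#'
#' @param ref The reference.
#' @param reads Read tibble or character vector (ignored when `alignments`
#'   is given).
#' @param alignments Optional pre-computed `read_alignments` (e.g. from
#'   [read_sam()]).
#' @param config A [pipeline_config()].
#' @return An `indel_run`: list with `alignments`, `profiles`, `track`,
#'   `candidates`, `confirmed`, and `report` (gamma, batch count, per-stage
#'   counts, effective parameters).
#' @export
run_pipeline <- function(ref, reads = NULL, alignments = NULL,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  ref <- as_reference(ref)
  if (is.null(alignments)) {
    if (is.null(reads)) abort("provide reads or alignments")
    alignments <- align_reads(reads, ref, max_mismatch = config$max_mismatch)
  }
  if (!is.na(alignments$read_length) &&
      alignments$read_length != config$read_length) {
    abort(sprintf("config read_length %d but reads are %d bp",
                  config$read_length, alignments$read_length))
  }
  prof <- compute_profiles(alignments, ref, trim = config$trim,
                           w_d = config$w_d, w_m = config$w_m)
  track <- detector_track(prof, w_f = config$w_f)
  confirmer <- function(pos) {
    confirm_candidates(pos, alignments$unaligned, ref, params = config$sw)
  }
  if (config$mode == "iterative") {
    it <- iterative_detection(track, confirmer, batch = config$batch,
                              per_site_cap = config$per_site_cap)
    candidates <- select_candidates(track, "top_n", n = it$n_tested,
                                    per_site_cap = config$per_site_cap)
    confirmed <- it$confirmed
    n_batches <- it$n_batches
  } else {
    candidates <- select_candidates(track, "top_n", n = config$top_n,
                                    per_site_cap = config$per_site_cap)
    confirmed <- confirmer(candidates$pos)
    n_batches <- 1L
  }
  structure(
    list(ref = ref, alignments = alignments, profiles = prof, track = track,
         candidates = candidates, confirmed = confirmed,
         report = list(
           n_reads = nrow(alignments$aligned) + nrow(alignments$unaligned),
           n_aligned = nrow(alignments$aligned),
           n_unaligned = nrow(alignments$unaligned),
           n_candidates = nrow(candidates),
           gamma = nrow(candidates) / nrow(track),
           n_batches = n_batches,
           n_confirmed = nrow(confirmed),
           config = config)),
    class = "indel_run")
}

#' @export
print.indel_run <- function(x, ...) {
  r <- x$report
  cat(sprintf("<indel_run> %s reads (%s aligned, %s unaligned pool)\n",
              format(r$n_reads, big.mark = ","),
              format(r$n_aligned, big.mark = ","),
              format(r$n_unaligned, big.mark = ",")))
  cat(sprintf("  %d candidates tested (gamma = %.4f, %d batch(es)); %d confirmed indel(s)\n",
              r$n_candidates, r$gamma, r$n_batches, r$n_confirmed))
  if (nrow(x$confirmed)) print(x$confirmed)
  invisible(x)
}

#' Annotate confirmed indels with zygosity and carrier fraction
#'
#' @param run An `indel_run`.
#' @param zygosity_model Optional [fit_zygosity()] model.
#' @param fraction_model Optional [fit_fraction()] model.
#' @param w_f Feature-extraction half-width (defaults to the run's `w_f`).
#' @return The confirmed-indel tibble with `d_hat`, `m1_hat` and the
#'   requested annotations appended.
#' @export
annotate_indels <- function(run, zygosity_model = NULL, fraction_model = NULL,
                            w_f = NULL) {
  stopifnot(inherits(run, "indel_run"))
  conf <- run$confirmed
  if (!nrow(conf)) return(conf)
  w_f <- w_f %||% run$report$config$w_f
  feat <- indel_features(run$profiles, conf$position, w_f = w_f)
  conf$d_hat <- feat$d_hat
  conf$m1_hat <- feat$m1_hat
  if (!is.null(zygosity_model)) {
    conf <- classify_zygosity(zygosity_model, conf)
  }
  if (!is.null(fraction_model)) {
    conf <- estimate_fraction(fraction_model, conf)
  }
  conf
}
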