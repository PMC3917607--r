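# Spike-in read simulation: random references, error-bearing reads, and
# fractional indel spiking with a ground-truth table for benchmarking.

#' Configuration for a spike-in simulation
#'
#' Describes one simulated sequencing lane: a random reference, uniformly
#' placed error-bearing reads, and one indel spiked into a chosen fraction of
#' the reads covering each of a set of well-separated positions. The spike
#' fraction models zygosity or tumor content: 1 for a homozygous indel, 0.5
#' for a heterozygote, lower for a variant diluted by wild-type cells.
#'
#' @param ref_length Reference length in bp.
#' @param read_length Read length L in bp.
#' @param n_reads Number of simulated reads.
#' @param errors_per_read Substitution errors introduced in each read
#'   (default 1, i.e. a per-base error rate of 1/L).
#' @param spike_positions Strictly increasing 1-based positions at which the
#'   indel is introduced. Each must be at least `read_length` from either
#'   reference end (deletions additionally `indel_size` from the 3' end) and
#'   consecutive positions must be more than `2 * read_length + indel_size`
#'   apart so spike footprints cannot overlap.
#' @param indel_size Indel size in bp.
#' @param indel_kind `"insertion"` or `"deletion"`.
#' @param spike_fraction Fraction of covering reads to modify, 0 or in (0, 1].
#' @param seed Integer seed; identical configurations reproduce byte-identical
#'   read sets.
#' @param error_weights Optional length-`read_length` vector of relative
#'   weights for the within-read position of sequencing errors (default
#'   uniform).
#' @return A `spike_config` object (a validated list).
#' @export
spike_config <- function(ref_length, read_length = 28, n_reads,
                         errors_per_read = 1, spike_positions = integer(),
                         indel_size = 1,
                         indel_kind = c("insertion", "deletion"),
                         spike_fraction = 0.5, seed = 1,
                         error_weights = NULL) {
  indel_kind <- match.arg(indel_kind)
  stopifnot(ref_length >= 1, read_length >= 1, n_reads >= 0,
            errors_per_read >= 0, indel_size >= 1)
  if (!(spike_fraction == 0 || (spike_fraction > 0 && spike_fraction <= 1))) {
    abort("spike_fraction must be 0 or in (0, 1]")
  }
  p <- as.integer(spike_positions)
  if (length(p)) {
    if (is.unsorted(p, strictly = TRUE)) {
      abort("spike_positions must be strictly increasing")
    }
    hi <- ref_length - read_length -
      if (indel_kind == "deletion") indel_size else 0L
    if (any(p < read_length) || any(p > hi)) {
      abort(sprintf("spike_positions must lie in [%d, %d]", read_length, hi))
    }
    if (length(p) > 1 && any(diff(p) <= 2 * read_length + indel_size)) {
      abort("consecutive spike_positions closer than 2L + indel size: footprints would overlap")
    }
  }
  if (!is.null(error_weights) && length(error_weights) != read_length) {
    abort("error_weights must have length read_length")
  }
  structure(
    list(ref_length = as.integer(ref_length),
         read_length = as.integer(read_length),
         n_reads = as.integer(n_reads),
         errors_per_read = as.integer(errors_per_read),
         spike_positions = p, indel_size = as.integer(indel_size),
         indel_kind = indel_kind, spike_fraction = spike_fraction,
         seed = as.integer(seed), error_weights = error_weights),
    class = "spike_config"
  )
}

#' @export
print.spike_config <- function(x, ...) {
  cat(sprintf(
    "<spike_config> %s bp ref, %s reads x %d bp, %d error(s)/read\n",
    format(x$ref_length, big.mark = ","), format(x$n_reads, big.mark = ","),
    x$read_length, x$errors_per_read))
  cat(sprintf("  %d x %d bp %s spiked at fraction %g (seed %d)\n",
              length(x$spike_positions), x$indel_size, x$indel_kind,
              x$spike_fraction, x$seed))
  invisible(x)
}

#' Simulate a random reference sequence
#'
#' Bases are i.i.d. uniform over A/C/G/T; the same seed reproduces the same
#' sequence.
#'
#' @param length Reference length in bp (positive).
#' @param seed Integer seed.
#' @param name Sequence name.
#' @return A [as_reference()] object.
#' @export
make_reference <- function(length, seed = 1, name = "ref") {
  if (length < 1) abort("reference length must be positive")
  seq <- withr::with_seed(seed, random_dna(length))
  as_reference(seq, name = name)
}

#' Simulate error-bearing short reads from a reference
#'
#' Reads are `read_length`-bp substrings with uniform start positions; each is
#' drawn from the forward or reverse strand with equal probability and stored
#' as observed (reverse-strand reads are reverse-complemented). Exactly
#' `errors_per_read` positions per read are substituted with a different base,
#' at uniform within-read positions unless `error_weights` is given. The true
#' origin of every read is recorded for benchmarking only; the detector never
#' sees it.
#'
#' @param ref Reference ([as_reference()] or string).
#' @param n_reads Number of reads.
#' @param read_length Read length L in bp (at most the reference length).
#' @param errors_per_read Substitutions per read.
#' @param seed Integer seed.
#' @param error_weights Optional within-read error position weights.
#' @return A tibble with columns `read_id`, `seq` (observed sequence),
#'   `true_start`, `true_strand`, and bookkeeping columns `err_pos`,
#'   `err_base` (forward-sense error positions/bases) used when indels are
#'   spiked into already-drawn reads.
#' @export
simulate_reads <- function(ref, n_reads, read_length = 28, errors_per_read = 1,
                           seed = 1, error_weights = NULL) {
  ref <- as_reference(ref)
  L <- as.integer(read_length)
  if (L > ref$length) abort("read_length exceeds reference length")
  if (n_reads < 0) abort("n_reads must be non-negative")
  n <- as.integer(n_reads)
  withr::with_seed(seed, {
    starts <- sample.int(ref$length - L + 1L, n, replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    fwd <- substring(ref$sequence, starts, starts + L - 1L)
    err_pos <- vector("list", n)
    err_base <- vector("list", n)
    if (errors_per_read == 1 && n > 0) {
      pos <- sample.int(L, n, replace = TRUE, prob = error_weights)
      old <- match(substring(fwd, pos, pos), DNA_BASES)
      new <- (old + sample.int(3L, n, replace = TRUE) - 1L) %% 4L + 1L
      err_pos <- as.list(pos)
      err_base <- as.list(DNA_BASES[new])
      fwd <- apply_errors(fwd, err_pos, err_base)
    } else if (errors_per_read > 0 && n > 0) {
      for (i in seq_len(n)) {
        pos <- sample.int(L, errors_per_read, prob = error_weights)
        old <- match(substring(fwd[i], pos, pos), DNA_BASES)
        new <- (old + sample.int(3L, errors_per_read, replace = TRUE) - 1L) %% 4L + 1L
        err_pos[[i]] <- pos
        err_base[[i]] <- DNA_BASES[new]
      }
      fwd <- apply_errors(fwd, err_pos, err_base)
    }
    obs <- fwd
    rev <- strand == "-"
    if (any(rev)) obs[rev] <- revcomp(fwd[rev])
    tibble(
      read_id = sprintf("read_%d", seq_len(n)), seq = obs,
      true_start = starts, true_strand = strand,
      err_pos = err_pos, err_base = err_base,
      spiked = FALSE, spike_pos = NA_integer_
    )
  })
}

apply_errors <- function(fwd, err_pos, err_base) {
  np <- lengths(err_pos)
  idx <- rep(seq_along(fwd), np)
  pos <- unlist(err_pos, use.names = FALSE)
  base <- unlist(err_base, use.names = FALSE)
  for (k in seq_len(max(np, 0))) {
    take <- which(np >= k)
    p <- vapply(err_pos[take], `[[`, integer(1), k)
    b <- vapply(err_base[take], `[[`, character(1), k)
    s <- fwd[take]
    substr(s, p, p) <- b
    fwd[take] <- s
  }
  fwd
}

#' Spike indels into a fraction of covering reads
#'
#' For each configured position `t`, a `spike_fraction` of the reads whose
#' footprint covers `t` (rounded to the nearest count, chosen uniformly at
#' random) is rewritten to carry the indel. Insertions insert one random
#' `indel_size`-bp string -- the same string for every modified read at a
#' position -- immediately after `t`; deletions remove reference bases
#' `t..t+size-1`. Modified reads are rebuilt from the locally mutated
#' reference so they keep length L (an insertion displaces 3' bases off the
#' read end; a deletion pulls 3' reference bases in), and the read's recorded
#' sequencing errors are re-applied. Reads in which the indel would fall
#' outside the read are not eligible for modification, so every selected read
#' genuinely carries the indel.
#'
#' @param reads Read tibble from [simulate_reads()].
#' @param ref The reference the reads were drawn from.
#' @param config A [spike_config()].
#' @return A list with `reads` (modified tibble) and `truth`, a tibble with
#'   one row per spike position: `position`, `kind`, `size`, `fraction`
#'   (target), `realized_fraction`, `n_covering`, `n_modified`, `bases`
#'   (inserted string or deleted reference bases).
#' @export
spike_indels <- function(reads, ref, config) {
  stopifnot(inherits(config, "spike_config"))
  ref <- as_reference(ref)
  X <- ref$sequence
  L <- config$read_length
  f <- config$spike_fraction
  kind <- config$indel_kind
  size <- config$indel_size
  s <- reads$true_start
  truth <- vector("list", length(config$spike_positions))
  withr::with_seed(derive_seed(config$seed, 1L), {
    for (z in seq_along(config$spike_positions)) {
      t <- config$spike_positions[z]
      covering <- which(s <= t & s + L - 1L >= t)
      if (!length(covering)) {
        abort(sprintf("spike position %d is not covered by any read", t))
      }
      eligible <- if (kind == "insertion") {
        covering[s[covering] >= t - L + 2L]
      } else {
        covering[s[covering] <= t - 1L]
      }
      n_mod <- min(round(f * length(covering)), length(eligible))
      sel <- if (n_mod > 0) sample(eligible, n_mod) else integer()
      bases <- if (kind == "insertion") random_dna(size) else
        substr(X, t, t + size - 1L)
      if (n_mod > 0) {
        ss <- s[sel]
        hap <- if (kind == "insertion") {
          paste0(substring(X, ss, t), bases, substring(X, t + 1L, t + L))
        } else {
          paste0(substring(X, ss, t - 1L), substring(X, t + size, t + size + L))
        }
        mut <- substr(hap, 1L, L)
        mut <- apply_errors(mut, reads$err_pos[sel], reads$err_base[sel])
        obs <- mut
        rev <- reads$true_strand[sel] == "-"
        if (any(rev)) obs[rev] <- revcomp(mut[rev])
        reads$seq[sel] <- obs
        reads$spiked[sel] <- TRUE
        reads$spike_pos[sel] <- t
      }
      truth[[z]] <- tibble(
        position = t, kind = kind, size = size, fraction = f,
        realized_fraction = n_mod / length(covering),
        n_covering = length(covering), n_modified = n_mod, bases = bases
      )
    }
  })
  list(reads = reads, truth = bind_rows(truth))
}

#' Simulate a complete spiked sequencing lane
#'
#' Convenience wrapper chaining [make_reference()], [simulate_reads()] and
#' [spike_indels()] with seeds derived from `config$seed`.
#'
#' @param config A [spike_config()].
#' @param ref Optional pre-built reference (defaults to a fresh random
#'   reference of `config$ref_length`).
#' @return A list with `ref`, `reads`, and `truth`.
#' @export
simulate_spiked_lane <- function(config, ref = NULL) {
  stopifnot(inherits(config, "spike_config"))
  ref <- ref %||% make_reference(config$ref_length, seed = derive_seed(config$seed, 2L))
  reads <- simulate_reads(ref, config$n_reads, config$read_length,
                          config$errors_per_read,
                          seed = derive_seed(config$seed, 3L),
                          error_weights = config$error_weights)
  if (length(config$spike_positions)) {
    sp <- spike_indels(reads, ref, config)
  } else {
    sp <- list(reads = reads,
               truth = tibble(position = integer(), kind = character(),
                              size = integer(), fraction = numeric(),
                              realized_fraction = numeric(),
                              n_covering = integer(), n_modified = integer(),
                              bases = character()))
  }
  list(ref = ref, reads = sp$reads, truth = sp$truth)
}
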