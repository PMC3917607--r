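# Independent oracles and shared fixtures for the test suite.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

rc <- function(x) indelscout::revcomp(x)

# exhaustive gapless placement search in plain R, with the package's tie
# rules (fewest mismatches, smallest start, forward strand first)
r_align_oracle <- function(ref, read, max_mm) {
  refv <- strsplit(ref, "")[[1]]
  best <- NULL
  for (s in seq_len(nchar(ref) - nchar(read) + 1)) {
    for (strand in c("+", "-")) {
      r <- if (strand == "+") read else rc(read)
      mm <- sum(refv[s:(s + nchar(read) - 1)] != strsplit(r, "")[[1]])
      if (mm <= max_mm &&
          (is.null(best) || mm < best$mm)) {
        best <- list(start = s, strand = strand, mm = mm)
      }
    }
  }
  best
}

# per-position re-count of trimmed depth
r_depth_oracle <- function(starts, L, T, trim) {
  vapply(seq_len(T), function(k) {
    sum(starts + trim <= k & starts + L - 1 - trim >= k)
  }, numeric(1))
}

# clipped-window median by direct re-sort
r_median_oracle <- function(x, hw) {
  n <- length(x)
  vapply(seq_len(n), function(k) {
    median(x[max(1, k - hw + 1):min(n, k + hw - 1)])
  }, numeric(1))
}

# Smith-Waterman score oracle; Biostrings prices a length-g gap as
# gapOpening + gapExtension * g while the package prices it as
# |gap_open| + |gap_extend| * (g - 1), hence the offset
sw_score_oracle <- function(read, segment, match = 2, mismatch = -3,
                            gap_open = -16, gap_extend = 0) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  s <- Biostrings::score(Biostrings::pairwiseAlignment(
    read, segment, type = "local", substitutionMatrix = mat,
    gapOpening = abs(gap_open) - abs(gap_extend),
    gapExtension = abs(gap_extend)))
  max(s, 0)
}

# fixture cache shared across test files (one R session per test_dir run)
.fixtures <- new.env(parent = emptyenv())
fixture <- function(name, maker) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, maker(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# a moderately deep amplicon lane with one spiked indel in the middle
amplicon_lane <- function(size, kind, fraction, seed, ref_length = 1500,
                          coverage = 300, read_length = 28) {
  n_reads <- round(coverage * ref_length / read_length)
  cfg <- spike_config(
    ref_length = ref_length, read_length = read_length, n_reads = n_reads,
    spike_positions = round(ref_length / 2), indel_size = size,
    indel_kind = kind, spike_fraction = fraction, seed = seed
  )
  simulate_spiked_lane(cfg)
}

# the scaled phiX-style lane used by several suites: 2,686 bp reference,
# 25 spike sites 100 bp apart, ~396x coverage
small_phix_config <- function(size, kind, fraction, seed, n_sites = 25) {
  spike_config(
    ref_length = 2686, read_length = 28, n_reads = 38000,
    spike_positions = seq(100L, by = 100L, length.out = n_sites),
    indel_size = size, indel_kind = kind, spike_fraction = fraction,
    seed = seed
  )
}

# run a lane through align -> profiles and return everything
profile_lane <- function(lane, max_mismatch = 2, trim = 8) {
  aln <- align_reads(lane$reads, lane$ref, max_mismatch = max_mismatch)
  prof <- compute_profiles(aln, lane$ref, trim = trim)
  list(lane = lane, aln = aln, prof = prof)
}

# spike-site features for genotype models at the true positions
lane_features <- function(cfg) {
  lane <- simulate_spiked_lane(cfg)
  pl <- profile_lane(lane)
  feat <- indel_features(pl$prof, lane$truth$position)
  feat$fraction <- cfg$spike_fraction
  feat
}
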