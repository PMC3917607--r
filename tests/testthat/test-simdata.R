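# Spike-in simulator: determinism, error model, spiking arithmetic, I/O.

test_that("make_reference draws uniform ACGT sequence reproducibly", {
  ref <- make_reference(10100, seed = 3)
  expect_equal(ref$length, 10100)
  expect_false(grepl("[^ACGT]", ref$sequence))
  expect_identical(make_reference(10100, seed = 3)$sequence, ref$sequence)
  expect_false(make_reference(10100, seed = 4)$sequence == ref$sequence)
  expect_equal(make_reference(5386, seed = 1)$length, 5386)
  expect_true(make_reference(1, seed = 1)$sequence %in% c("A", "C", "G", "T"))
  expect_error(make_reference(0), "positive")
})

test_that("simulated reads are L-bp substrings with exactly the requested errors", {
  ref <- make_reference(2000, seed = 7)
  reads <- simulate_reads(ref, 500, read_length = 28, errors_per_read = 1,
                          seed = 1)
  expect_equal(nrow(reads), 500)
  expect_true(all(nchar(reads$seq) == 28))
  # recover forward-sense and count mismatches vs the true origin
  fwd <- ifelse(reads$true_strand == "-", revcomp(reads$seq), reads$seq)
  origin <- substring(ref$sequence, reads$true_start, reads$true_start + 27)
  mm <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, fwd, origin)
  expect_true(all(mm == 1))
  # empirical per-base error rate is 1/L by construction
  expect_equal(sum(mm) / (500 * 28), 1 / 28)
  # both strands drawn
  expect_true(all(c("+", "-") %in% reads$true_strand))

  clean <- simulate_reads(ref, 200, 28, errors_per_read = 0, seed = 2)
  cf <- ifelse(clean$true_strand == "-", revcomp(clean$seq), clean$seq)
  expect_identical(cf, substring(ref$sequence, clean$true_start,
                                 clean$true_start + 27))
  expect_error(simulate_reads(ref, 10, read_length = 3000), "exceeds")
})

test_that("simulation is deterministic given the configuration seed", {
  cfg <- spike_config(ref_length = 1200, n_reads = 3000,
                      spike_positions = c(400, 800), indel_size = 2,
                      indel_kind = "deletion", spike_fraction = 0.5, seed = 9)
  a <- simulate_spiked_lane(cfg)
  b <- simulate_spiked_lane(cfg)
  expect_identical(a$ref$sequence, b$ref$sequence)
  expect_identical(a$reads$seq, b$reads$seq)
  expect_identical(a$truth, b$truth)
})

test_that("spiking modifies the rounded fraction of covering reads and keeps length L", {
  ref <- make_reference(1500, seed = 5)
  reads <- simulate_reads(ref, 6000, 28, 1, seed = 6)
  for (kind in c("insertion", "deletion")) {
    cfg <- spike_config(ref_length = 1500, n_reads = 6000,
                        spike_positions = c(500, 900), indel_size = 3,
                        indel_kind = kind, spike_fraction = 0.25, seed = 8)
    sp <- spike_indels(reads, ref, cfg)
    expect_true(all(nchar(sp$reads$seq) == 28))
    for (i in seq_len(nrow(sp$truth))) {
      t <- sp$truth$position[i]
      covering <- sum(reads$true_start <= t & reads$true_start + 27 >= t)
      expect_equal(sp$truth$n_covering[i], covering)
      # modified count within one read of the rounded target (eligibility
      # can remove at most the single boundary start)
      expect_lte(abs(sp$truth$n_modified[i] - round(0.25 * covering)), 1)
      expect_equal(sum(sp$reads$spiked & sp$reads$spike_pos == t,
                       na.rm = TRUE),
                   sp$truth$n_modified[i])
    }
    # spiked reads differ from their unspiked version (a deletion whose
    # junction sits at the very last base can coincide by chance)
    changed <- sp$reads$seq != reads$seq
    expect_gt(mean(changed[sp$reads$spiked]), 0.95)
  }
})

test_that("every modified read genuinely carries the indel", {
  ref <- make_reference(1200, seed = 21)
  reads <- simulate_reads(ref, 5000, 28, 0, seed = 22)
  cfg <- spike_config(ref_length = 1200, n_reads = 5000,
                      spike_positions = 600, indel_size = 2,
                      indel_kind = "insertion", spike_fraction = 1, seed = 23)
  sp <- spike_indels(reads, ref, cfg)
  ins <- sp$truth$bases[1]
  mod <- sp$reads[sp$reads$spiked, ]
  fwd <- ifelse(mod$true_strand == "-", revcomp(mod$seq), mod$seq)
  # the inserted string appears right after position 600 in every carrier
  offset <- 600 - mod$true_start + 2
  visible <- substring(paste0(ins, "XX"), 1, pmin(2, 28 - offset + 1))
  expect_true(all(substr(fwd, offset, offset + 1) == visible))
})

test_that("null spikes and invalid configurations behave per contract", {
  ref <- make_reference(1000, seed = 2)
  reads <- simulate_reads(ref, 2000, 28, 1, seed = 3)
  cfg0 <- spike_config(ref_length = 1000, n_reads = 2000,
                       spike_positions = 500, indel_size = 1,
                       indel_kind = "insertion", spike_fraction = 0, seed = 1)
  sp0 <- spike_indels(reads, ref, cfg0)
  expect_identical(sp0$reads$seq, reads$seq)
  expect_equal(sp0$truth$n_modified, 0)

  expect_error(spike_config(ref_length = 1000, n_reads = 100,
                            spike_positions = c(500, 520), indel_size = 1,
                            indel_kind = "insertion", spike_fraction = 0.5),
               "footprints")
  expect_error(spike_config(ref_length = 1000, n_reads = 100,
                            spike_positions = c(990), indel_size = 1,
                            indel_kind = "insertion", spike_fraction = 0.5),
               "lie in")
  expect_error(spike_config(ref_length = 1000, n_reads = 100,
                            spike_positions = 500, indel_size = 1,
                            indel_kind = "insertion", spike_fraction = 1.5),
               "spike_fraction")
  # a position no read covers
  tiny <- simulate_reads(ref, 1, 28, 0, seed = 4)
  cfg <- spike_config(ref_length = 1000, n_reads = 1, spike_positions = 500,
                      indel_size = 1, indel_kind = "insertion",
                      spike_fraction = 1, seed = 1)
  if (!(tiny$true_start <= 500 && tiny$true_start + 27 >= 500)) {
    expect_error(spike_indels(tiny, ref, cfg), "not covered")
  }
})

test_that("FASTA/FASTQ/truth files round-trip", {
  dir <- withr::local_tempdir()
  lane <- simulate_spiked_lane(
    spike_config(ref_length = 800, n_reads = 300, spike_positions = 400,
                 indel_size = 1, indel_kind = "deletion",
                 spike_fraction = 0.5, seed = 12))
  fa <- file.path(dir, "ref.fasta")
  fq <- file.path(dir, "reads.fastq")
  tsv <- file.path(dir, "truth.tsv")
  write_reference_fasta(lane$ref, fa)
  write_reads_fastq(lane$reads, fq)
  write_spike_truth(lane$truth, tsv)
  expect_identical(read_reference_fasta(fa)$sequence, lane$ref$sequence)
  back <- read_reads_fastq(fq)
  expect_identical(back$seq, lane$reads$seq)
  expect_identical(back$read_id, lane$reads$read_id)
  tr <- read_spike_truth(tsv)
  expect_equal(tr$position, lane$truth$position)
  expect_equal(tr$bases, lane$truth$bases)
})
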