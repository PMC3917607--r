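# Smith-Waterman alignment, shared-gap confirmation, flanking k-mer check.

test_that("sw_align scores equal the independent local-alignment oracle", {
  withr::with_seed(61, {
    for (i in 1:60) {
      seg <- rand_dna(sample(40:200, 1))
      kind <- sample(c("random", "excised", "mutated"), 1)
      read <- switch(kind,
        random = rand_dna(sample(15:60, 1)),
        excised = { s <- sample(nchar(seg) - 30, 1)
                    r <- substr(seg, s, s + 29)
                    paste0(substr(r, 1, 12), substr(r, 16, 30)) },
        mutated = { s <- sample(nchar(seg) - 27, 1)
                    r <- substr(seg, s, s + 27)
                    p <- sample(28, 1)
                    substr(r, p, p) <- sample(c("A", "C", "G", "T"), 1)
                    r })
      for (par in list(sw_params(), sw_params(gap_open = -5),
                       sw_params(gap_open = -8, gap_extend = -2))) {
        expect_equal(sw_align(read, seg, par)$score,
                     sw_score_oracle(read, seg, par$match, par$mismatch,
                                     par$gap_open, par$gap_extend))
      }
    }
  })
})

test_that("a gapless perfect read scores L * match and an excision is recovered", {
  withr::with_seed(62, {
    seg <- rand_dna(120)
    read <- substr(seg, 31, 58)
    a <- sw_align(read, seg)
    expect_equal(a$score, 28 * 2)
    expect_equal(a$n_gaps, 0)
    expect_equal(a$seg_start, 31)

    # excise 3 bp from the middle of a segment copy
    read2 <- paste0(substr(seg, 31, 44), substr(seg, 48, 61))
    a2 <- sw_align(read2, seg)
    expect_equal(a2$n_gaps, 1)
    expect_equal(a2$gaps$kind, "deletion")
    expect_equal(a2$gaps$size, 3)
    # the reported interval reproduces the read when removed from the segment
    expect_equal(paste0(substr(seg, 31, a2$gaps$ref_start - 1),
                        substr(seg, a2$gaps$ref_end + 1, 61)), read2)
  })
})

test_that("gaps are left-normalized so homopolymer indels share one interval", {
  seg <- "ACGTTTTTACGGACTA"
  # delete one T of the run: any placement is equivalent; expect leftmost
  read <- "ACGTTTTACGGACTA"
  a <- sw_align(read, seg, sw_params(gap_open = -5))
  expect_equal(a$n_gaps, 1)
  expect_equal(a$gaps$ref_start, 4)
  expect_equal(a$gaps$ref_end, 4)
  # insert one extra T: anchored before the run
  read2 <- "ACGTTTTTTACGGACTA"
  a2 <- sw_align(read2, seg, sw_params(gap_open = -5))
  expect_equal(a2$n_gaps, 1)
  expect_equal(a2$gaps$kind, "insertion")
  expect_equal(a2$gaps$ref_start, 3)
  expect_error(sw_align("", seg), "empty")
})

test_that("confirmation finds a fully spiked insertion with the right size and bases", {
  lane <- fixture("amp_ins2_100", function() amplicon_lane(2, "insertion", 1, 63))
  aln <- align_reads(lane$reads, lane$ref)
  expect_equal(nrow(confirm_candidate(750, tibble::tibble(read_id = character(),
                                                          seq = character()),
                                      lane$ref)), 0)
  conf <- confirm_candidate(lane$truth$position[1], aln$unaligned, lane$ref)
  expect_equal(nrow(conf), 1)
  expect_equal(conf$kind, "insertion")
  expect_equal(conf$size, 2)
  expect_lte(abs(conf$position - lane$truth$position[1]), 5)
  expect_equal(conf$bases, lane$truth$bases[1])
  expect_gte(conf$support, 5)
  # candidates too near the reference end are refused with a diagnostic
  expect_warning(out <- confirm_candidate(10, aln$unaligned, lane$ref),
                 "reference end")
  expect_equal(nrow(out), 0)
})

test_that("a heterozygous 14 bp deletion is confirmed at full size (gap extend 0)", {
  lane <- fixture("amp_del14_50", function() amplicon_lane(14, "deletion", 0.5, 64))
  aln <- align_reads(lane$reads, lane$ref)
  t <- lane$truth$position[1]
  conf <- confirm_candidate(t, aln$unaligned, lane$ref)
  expect_equal(conf$kind, "deletion")
  expect_equal(conf$size, 14)
  expect_lte(abs(conf$position - t), 5)
  # with a positive extension penalty the same candidate fails: the gap
  # becomes costlier than discarding a flank
  conf2 <- confirm_candidate(t, aln$unaligned, lane$ref,
                             sw_params(gap_extend = -2))
  expect_true(nrow(conf2) == 0 || conf2$size != 14)
})

test_that("confirmation is sound on indel-free lanes", {
  fx <- fixture("null_pool", function() {
    ref <- make_reference(3000, seed = 65)
    # 3 errors per read so that the unaligned pool is non-empty without
    # any indel in the data
    reads <- simulate_reads(ref, 25000, 28, 3, seed = 66)
    list(ref = ref, aln = align_reads(reads, ref))
  })
  expect_gt(nrow(fx$aln$unaligned), 50)
  pos <- withr::with_seed(67, sample(100:2900, 150))
  conf <- confirm_candidates(pos, fx$aln$unaligned, fx$ref)
  expect_lte(nrow(conf), floor(0.001 * 150))
})

test_that("batched confirmation equals the per-candidate path", {
  lane <- fixture("amp_ins2_100", function() amplicon_lane(2, "insertion", 1, 63))
  aln <- align_reads(lane$reads, lane$ref)
  t <- lane$truth$position[1]
  pos <- c(t - 2, t, t + 30, 200)
  batch <- confirm_candidates(pos, aln$unaligned, lane$ref)
  single <- dplyr::bind_rows(lapply(pos, confirm_candidate,
                                    pool = aln$unaligned, ref = lane$ref))
  single <- dplyr::slice_max(dplyr::group_by(single, kind, ref_start, ref_end),
                             support, n = 1, with_ties = FALSE)
  expect_equal(batch$position, single$position)
  expect_equal(batch$support, single$support)
})

test_that("flanking k-mer confirmation sizes indels and ignores clean data", {
  clean <- fixture("clean_small", function() {
    ref <- make_reference(1000, seed = 68)
    list(ref = ref, reads = simulate_reads(ref, 4000, 28, 1, seed = 69))
  })
  out <- flank_kmer_confirm(500, clean$reads, clean$ref)
  expect_true(is.na(out$delta))

  ins <- fixture("amp_ins2_100", function() amplicon_lane(2, "insertion", 1, 63))
  t <- ins$truth$position[1]
  reads_near <- ins$reads[abs(ins$reads$true_start + 14 - t) < 60, ]
  oi <- flank_kmer_confirm(t, reads_near, ins$ref)
  expect_equal(oi$delta, 2)
  expect_equal(oi$n_votes, oi$n_informative)  # unanimous at 100% spike

  del <- fixture("amp_del14_50", function() amplicon_lane(14, "deletion", 0.5, 64))
  td <- del$truth$position[1]
  reads_near_d <- del$reads[abs(del$reads$true_start + 14 - td) < 60, ]
  od <- flank_kmer_confirm(td, reads_near_d, del$ref)
  expect_equal(od$delta, -14)
  expect_gt(od$n_votes, od$n_informative / 2)
})
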