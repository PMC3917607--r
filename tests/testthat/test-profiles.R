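# Depth/mismatch tracks, median smoothing, normalization.

aln_from <- function(reads, ref, ...) align_reads(reads, ref, ...)

test_that("trimmed depth counts the footprint arithmetic correctly", {
  ref <- make_reference(60, seed = 41)
  read <- substr(ref$sequence, 1, 28)
  aln <- aln_from(read, ref)
  d <- depth_track(aln, trim = 8)
  expect_equal(which(d$depth == 1), 9:20)
  expect_equal(which(d$depth_untrimmed == 1), 1:28)
  expect_equal(sum(d$depth), 12)
  expect_error(depth_track(aln, trim = 14), "trim")
})

test_that("depth equals the brute-force per-position count on a random fixture", {
  ref <- make_reference(700, seed = 42)
  reads <- simulate_reads(ref, 900, 28, 1, seed = 43)
  aln <- aln_from(reads, ref)
  d <- depth_track(aln, trim = 8)
  expect_equal(d$depth, r_depth_oracle(aln$aligned$start, 28, 700, 8))
  expect_equal(d$depth_untrimmed, r_depth_oracle(aln$aligned$start, 28, 700, 0))
})

test_that("mismatch tracks follow the alignment representation", {
  # X = 'AGGTTC', read 'GTT' aligned at 3: matches everywhere, empty
  # mismatch vector
  ref <- as_reference("AGGTTC")
  aln <- align_reads(tibble::tibble(read_id = "r1", seq = "GTT"), ref,
                     max_mismatch = 0)
  m <- mismatch_tracks(aln, ref)
  expect_equal(aln$aligned$start, 3L)
  expect_equal(m$m_g[3], 1)
  expect_equal(m$m1[3], 0)
  expect_equal(m$m2[3], 0)
  expect_equal(m$m1, rep(0, 6))

  # a substituted base lands in the right mismatch bucket; the placement
  # tie (1 mismatch at start 2 or 3) resolves to the smaller start
  aln2 <- align_reads("GAT", ref, max_mismatch = 1)
  expect_equal(aln2$aligned$start, 2L)
  m2 <- mismatch_tracks(aln2, ref)
  expect_equal(m2$m_a[3], 1)
  expect_equal(m2$m1[3], 1)  # ref G at 3, observed A
})

test_that("m1 tallies match a brute-force recount on a spiked fixture", {
  lane <- fixture("lane_ins2_50", function() {
    simulate_spiked_lane(spike_config(
      ref_length = 1200, n_reads = 8000, spike_positions = 600,
      indel_size = 2, indel_kind = "insertion", spike_fraction = 0.5,
      seed = 44))
  })
  aln <- aln_from(lane$reads, lane$ref)
  m <- mismatch_tracks(aln, lane$ref)
  # brute force: tally observed bases per position
  T <- lane$ref$length
  tal <- matrix(0L, 4, T, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_len(nrow(aln$aligned))) {
    s <- aln$aligned$start[i]
    b <- strsplit(aln$aligned$seq_fwd[i], "")[[1]]
    for (j in seq_along(b)) tal[b[j], s + j - 1] <- tal[b[j], s + j - 1] + 1L
  }
  refv <- strsplit(lane$ref$sequence, "")[[1]]
  m1_oracle <- vapply(seq_len(T), function(k) {
    max(tal[setdiff(rownames(tal), refv[k]), k])
  }, integer(1))
  expect_equal(m$m1, m1_oracle)
  expect_equal(unname(m$m_a), unname(tal["A", ]))
})

test_that("median smoothing matches the naive clipped-window oracle", {
  expect_equal(median_smooth(rep(4, 50), 7), rep(4, 50))
  x <- rep(10, 101); x[48:52] <- 0
  expect_equal(median_smooth(x, 20), rep(10, 101))  # narrow dip removed
  withr::with_seed(45, {
    y <- rpois(400, 30)
    expect_equal(median_smooth(y, 29), r_median_oracle(y, 29))
    expect_equal(median_smooth(y, 3), r_median_oracle(y, 3))
    z <- runif(40)
    expect_equal(median_smooth(z, 25), r_median_oracle(z, 25))  # window > track
  })
  expect_error(median_smooth(numeric(), 5), "empty")
})

test_that("normalization arithmetic, gating and degenerate cases", {
  prof <- tibble::tibble(
    pos = 1:3, depth = c(10, 0, 5), d_bar = c(20, 0, 10),
    m1 = c(10, 10, 4), m2 = c(5, 0, 1), m1_bar = c(4, 5, 0)
  )
  out <- normalize_profiles(prof)
  expect_equal(out$m1_hat[1], 0)          # 10 is not > 2 * 5: gate closes
  expect_equal(out$m1_hat[2], 2)          # 10 / 5, gate open
  expect_equal(out$m1_hat[3], 4)          # m1_bar floored at 1
  expect_equal(out$d_hat[1], 0.5)
  expect_equal(out$d_hat[2], 0)           # uncovered
  expect_true(out$uncovered[2])
  expect_error(normalize_profiles(prof[, 1:2]), "smooth")
})

test_that("an indel-free lane has flat normalized depth and windows obey the 2L rule", {
  fx <- fixture("clean_lane", function() {
    ref <- make_reference(2000, seed = 46)
    reads <- simulate_reads(ref, 20000, 28, 1, seed = 47)
    profile_lane(list(ref = ref, reads = reads))
  })
  interior <- 200:1800
  expect_lt(max(abs(fx$prof$d_hat[interior] - 1)), 0.35)
  expect_lt(median(abs(fx$prof$d_hat[interior] - 1)), 0.1)
  expect_error(smooth_profiles(position_profiles(fx$aln, fx$lane$ref),
                               w_d = 56), "2 \\* read_length")
})

test_that("normalized tracks are invariant to duplicating every read", {
  lane <- fixture("lane_ins2_50", function() {
    simulate_spiked_lane(spike_config(
      ref_length = 1200, n_reads = 8000, spike_positions = 600,
      indel_size = 2, indel_kind = "insertion", spike_fraction = 0.5,
      seed = 44))
  })
  aln <- aln_from(lane$reads, lane$ref)
  doubled <- lane$reads
  doubled$read_id <- paste0("dup_", doubled$read_id)
  aln2 <- aln_from(dplyr::bind_rows(lane$reads, doubled), lane$ref)
  p1 <- compute_profiles(aln, lane$ref)
  p2 <- compute_profiles(aln2, lane$ref)
  expect_equal(p2$depth, 2 * p1$depth)
  expect_equal(p2$d_hat, p1$d_hat)
  expect_equal(p2$m1_hat, p1$m1_hat)
})

test_that("depth geometry at a fully spiked indel: ramps, plateau, trimmed zero", {
  ins <- fixture("lane_ins1_100", function() {
    simulate_spiked_lane(spike_config(
      ref_length = 1600, n_reads = 16000, spike_positions = 800,
      indel_size = 1, indel_kind = "insertion", spike_fraction = 1,
      seed = 48))
  })
  pl <- profile_lane(ins)
  t <- 800L; L <- 28L
  d <- pl$prof$depth_untrimmed
  # untrimmed depth drops towards t and recovers after, staying positive
  # (edge-effect alignments)
  left <- stats::lm(y ~ x, data = data.frame(x = (t - L):t, y = d[(t - L):t]))
  right <- stats::lm(y ~ x, data = data.frame(x = t:(t + L), y = d[t:(t + L)]))
  expect_lt(coef(left)[2], -5)
  expect_gt(coef(right)[2], 5)
  expect_gt(min(d[(t - 5):(t + 5)]), 0)
  expect_lt(d[t], 0.5 * median(d[c(400:700, 900:1200)]))
  # trimmed depth reaches zero at the indel
  expect_equal(min(pl$prof$depth[(t - 3):(t + 3)]), 0)

  del <- fixture("lane_del10_100", function() {
    simulate_spiked_lane(spike_config(
      ref_length = 1600, n_reads = 16000, spike_positions = 800,
      indel_size = 10, indel_kind = "deletion", spike_fraction = 1,
      seed = 49))
  })
  pd <- profile_lane(del)$prof$depth_untrimmed
  t1 <- 800L; t2 <- 809L
  flank <- median(pd[c(300:700, 900:1300)])
  # depth ramps down into t1 and stays depressed across the deleted
  # interval (reads starting inside the interval are drawn from the
  # reference and partially refill it, so the floor is lowest at t1)
  dleft <- stats::lm(y ~ x, data = data.frame(x = (t1 - L):t1,
                                              y = pd[(t1 - L):t1]))
  expect_lt(coef(dleft)[2], -5)
  expect_lt(pd[t1], 0.35 * flank)
  expect_true(all(pd[t1:t2] < 0.8 * flank))
  expect_lte(abs(which.min(pd[(t1 - 20):(t2 + 20)]) + (t1 - 21L) - t1), 3)
})
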