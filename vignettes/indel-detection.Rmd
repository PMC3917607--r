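---
title: "Two-step indel detection from mismatch-only alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step indel detection from mismatch-only alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indelscout)
library(dplyr)
```

## The problem

Deep targeted resequencing reads a small genomic region at fold coverages in
the hundreds with short single-end reads (here, 28 bp). The fast aligners of
that setting (ELAND, MAQ configured for mismatches only) place each read
gaplessly and tolerate a small number of substitutions, typically two. They
are fast precisely because they never open a gap -- and therefore they
cannot call an insertion or deletion (indel) directly. Running a gapped
aligner such as Smith--Waterman over every read against the whole target is
orders of magnitude more expensive.

This package detects indels *from the artifacts the gapless aligner leaves
behind*, and only then spends gapped-alignment effort on a few dozen short
reference segments. An indel carried by a fraction of the sample's DNA --
one allele of a heterozygote, or a somatic variant diluted by normal tissue
-- produces two local signatures in gapless output:

* a **depth drop**: a read whose indel sits near its centre cannot be placed
  within the mismatch tolerance anywhere, so coverage falls in a triangular
  ramp from `t - L` to the indel at `t` (and stays low across a deleted
  interval before recovering by `t + L`);
* an **edge-mismatch pile-up**: a read whose indel sits within a couple of
  bases of one end *does* align, converting the indel into a short run of
  terminal mismatches. These runs agree on the shifted base, so one
  alternative letter dominates the mismatch counts at the indel boundary.

## Step 1: the indel detector function

For every reference position `k` the package computes, from the gapless
alignments:

* `d(k)` -- depth counted on reads trimmed by 8 bp at both ends. Trimming
  removes exactly the edge-effect placements, so at a fully carried indel
  the trimmed depth reaches 0 while raw depth stays positive;
* `m_z(k)` -- counts of each observed letter; the mismatch vector is the 3
  counts for letters other than the reference base, with `m1 >= m2` its two
  largest components.

Coverage and error rates drift along any real target, so both tracks are
normalized by their local medians over windows of half-width `w_d = w_m =
2L + 1` (the windows must exceed `2L`, or the median itself is dragged down
inside a deletion's footprint): `d_hat = d / d_bar` and

    m1_hat(k) = (m1(k) / m1_bar(k)) * [m1(k) > 2 m2(k)].

The indicator is the error filter: a sequencing-error column spreads its
counts over all three alternative letters, an indel edge concentrates on
one. The detector function is the windowed ratio

    f(k) = sum_{|j - k| <= w_f} m1_hat(j) / d_hat(k),

large where mismatches concentrate *and* depth drops. Candidates are the
top-ranked positions by `f`.

Numerical choices worth stating:

* where `d_bar = 0` the position is flagged uncovered and can never become
  a candidate; `m1_bar` is floored at 1 (a locally clean lane must not blow
  up the ratio);
* in `f`, `d_hat` is floored at one read's worth (`1 / d_bar`): trimmed
  depth 0 is the *strongest* signal and must rank highest finite, not
  divide by zero;
* positions within one read length of a reference end are excluded -- depth
  is structurally truncated there and no read can bracket an indel;
* `w_f = 5` bp by default. The edge-mismatch shoulder produced by a
  2-mismatch tolerance spans at most a few bases on either side of the
  indel boundary; `w_f` only needs to cover it, and results are flat in a
  sweep over 3--10;
* no more than 8 candidates may fall inside any `2L` window (ties in `f`
  go to the smaller position). Without this cap the strongest site consumes
  an entire candidate budget.

Instead of fixing a threshold on `f`, `iterative_detection()` submits
candidates to step 2 in rank-ordered batches of 200 and stops after the
first batch that confirms nothing. False positives in step 1 are cheap --
step 2 removes them -- so classical error-rate control on `f` would be
misdirected effort.

## Step 2: Smith--Waterman confirmation by shared gaps

Reads that failed gapless alignment form the pool `S0`; at a true indel the
centrally carrying reads all land there. For each candidate `p` the package
extracts the segment `X[p - 40, p + 40]`, screens the pool for reads
sharing an exact 10-mer with it (a supporting alignment of a 28 bp read
must contain an exact run of at least 10 bases, so this screen cannot lose
a supporter -- it only bounds the number of gapped alignments), and aligns
the survivors locally in both orientations.

A read *supports* a gap when its alignment has exactly one gap, at most one
mismatch ("fewer than two"), and the gap interval lies within 5 bp of the
candidate. Each gap is first shifted to its leftmost equivalent position so
that the same physical indel lands on the same reference interval in every
read; without this, gaps inside homopolymer runs scatter across equivalent
placements and the vote fragments. A candidate is confirmed when more than
`M = 4` reads share one interval; the shared interval -- not the candidate
-- is the reported position, its length the reported size, and for
insertions the inserted string is the modal gap content across supporters
(a sequencing error adjacent to the insertion can distort any single
read's gap).

### Alignment scoring

Only one scoring parameter is externally dictated by the method: the gap
*extension* penalty is 0, so a gap costs its opening only and a 28 bp
deletion confirms exactly as readily as a 1 bp one. The remaining defaults
are match +2, mismatch -3, gap open -16. The opening penalty is chosen so
that a gap pays for itself only when anchored by more than
`|gap_open| / (2 * match)` = 8 matching bases on its *short* side:

* a deletion leaves the full read intact, flanks summing to 28 bases, so
  supporters with a centred junction are plentiful for any size up to `L`;
* an insertion of `g` bases leaves only `28 - g` read bases of reference
  sequence. For `g >= 12` no read can anchor 9 bases on both sides, the
  gapless single-flank alignment wins, and confirmation fails -- while
  step 1 still flags the site. This reproduces the observed behaviour of
  the method (long insertions detected but not confirmed; their rescue is
  localized assembly, out of scope here). With a weak opening penalty
  (say -5) long insertions would confirm readily, which is *not* what the
  reference results show.

The faster alignment-free alternative, `flank_kmer_confirm()`, compares the
distance between two unique flanking 6-mers in the reference and in the
reads containing both; the shared difference is the signed indel size. The
flanks must both sit outside the indel, whose extent is unknown, so the
downstream flank is scanned over small offsets and the first offset with a
strict nonzero majority wins. It is most effective at high carrier
fractions; at 50% the wild-type reads vote 0 against small insertions, and
the Smith--Waterman route is the robust default.

## Zygosity and carrier fraction

At a confirmed indel, the pair `(d_hat, m1_hat)` -- normalized depth at the
site, normalized gated mismatch peak within `w_f` of it (the mismatch spike
sits at the indel *boundary*, not its centre) -- separates carrier
fractions: depth falls and the mismatch peak rises with the fraction of
reads carrying the indel.

* `fit_zygosity()` is a two-feature Fisher linear discriminant (pooled
  within-class scatter over total *n*, so a duplicated training set gives
  the identical boundary) separating heterozygous (~50%) from homozygous
  (~100%) indels; exact boundary ties are called heterozygous. It is
  cross-checked against `MASS::lda()` in the test suite.
* `fit_fraction()` models a continuous carrier fraction as
  `logit(p) = alpha + beta * d_hat + delta * m1_hat`, fitted by
  quasi-likelihood logistic regression (responses are fractions in (0, 1],
  not counts). On spike-in data `beta` is negative and `delta` positive,
  and predictions are monotone accordingly.

Both are evaluated by repeated random 50/50 train/test splits
(`zygosity_split_error()`, `fraction_split_error()`, 100 splits by
default). On the scaled spike-in protocol below, the discriminant's mean
held-out misclassification is ~0--1% and the fraction model's held-out mean
absolute error ~5--7 percentage points, with the 25% and 50% classes the
hardest -- their feature spread is widest.

## What the simulator emulates

`simulate_spiked_lane()` reproduces the spike-in protocol that the
benchmark figures are defined on:

* a uniform-random reference (the phiX-sized experiments use 5,386 bp; the
  larger simulation 10,100 bp);
* `L = 28` bp reads at uniform positions, half from each strand, stored as
  observed (reverse-complemented) sequence;
* exactly one substitution error per read at a uniform within-read position
  (~3.6% per base -- deliberately pessimistic relative to real lanes; an
  optional weight vector can skew error positions if a machine profile is
  available);
* at each spike position, the target fraction of covering reads (rounded
  to the nearest count) is rewritten from the locally mutated reference:
  the *same* random insertion string for all carriers at a site, deletions
  refilled from downstream reference so every read keeps length `L`. Reads
  in which the indel would fall outside the read are not eligible, so
  every selected read genuinely carries it.

Features of real data it does **not** model: base-quality structure, indel
sequencing errors, PCR duplicates, paired ends, non-uniform coverage from
capture or amplicon boundaries, and context-dependent error hotspots.
Passing the replication suite therefore shows the *method* behaves as
described under its stated conditions; it does not certify performance on
any particular instrument's error profile. Two knock-on effects worth
knowing: (1) read-level spiking leaves reads that start strictly inside a
deleted interval unmodified, so wide deletions refill gradually instead of
staying perfectly flat; (2) with one error per read and a 2-mismatch
tolerance, almost no carrier of an insertion longer than ~12 bp aligns
even via the edge effect at 50% spike, so the long-insertion regression is
exercised at full spike where the signal is unambiguous.

## Problem sizes used in the checks

The replication suite runs the full protocol -- 5,386 bp reference, 50
spike sites 100 bp apart, 76,000 reads (~396x) -- for the headline
sensitivity/specificity conditions, and a half-size lane (2,686 bp, 25
sites, the same 396x coverage) for the feature-model protocols and
benchmark-grid properties; coverage, not reference length, drives every
per-site distribution. The acceptance script averages the 25%-spike grid
over three seeds per condition.

## Known limitations

* Insertions approaching the read length are flagged by step 1 but cannot
  be confirmed by local alignment of 28 bp reads; localized assembly would
  be the continuation.
* At the protocol's elevated error rate, the `m1 > 2 m2` gate costs step 1
  a few weakly covered true sites at 25% spike; sensitivities there sit a
  few points below the figures obtained from real (cleaner) lane data.
* The confirmed position is the left-normalized shared gap; in long
  homopolymer or repeat context it can sit several bases left of the
  physical event (standard VCF left-alignment semantics).
* Coordinates are 1-based and inclusive throughout; VCF output anchors
  deletions at the preceding base per convention.

## A worked miniature

```{r mini, eval = FALSE}
cfg <- spike_config(
  ref_length = 2000, n_reads = 16000, spike_positions = c(500, 1200),
  indel_size = 3, indel_kind = "deletion", spike_fraction = 0.5, seed = 91
)
lane <- simulate_spiked_lane(cfg)
run <- run_pipeline(lane$ref, lane$reads)
run$confirmed
annotate_indels(run)
autoplot(run$track, run$candidates)
```
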