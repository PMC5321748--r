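paf_line <- function(q, ql, qs, qe, strand, t, tl, ts, te, nm, bl, mq = 60) {
  paste(q, ql, qs, qe, strand, t, tl, ts, te, nm, bl, mq, sep = "\t")
}

test_that("PAF records map onto alignment rows; empty streams yield no batches", {
  p <- tempfile()
  writeLines(paf_line("r1", 5000, 100, 4900, "+", "ctg1", 20000, 1000, 5800,
                      4500, 4800), p)
  aln <- read_paf(p)
  expect_identical(nrow(aln), 1L)
  expect_identical(aln$read_start, 100)
  expect_identical(aln$contig_end, 5800)
  expect_identical(aln$matched_bases, 4500)

  writeLines(character(), p)
  expect_identical(length(alignment_batches(read_paf(p))), 0L)

  writeLines(c(paf_line("r1", 5000, 0, 100, "+", "c", 200, 0, 100, 90, 100),
               "garbage line"), p)
  expect_warning(aln2 <- read_paf(p), "skipped 1")
  expect_identical(nrow(aln2), 1L)
})

test_that("SAM clip-walk yields read intervals in original read orientation", {
  sam <- tempfile()
  seq500 <- strrep("A", 400)
  writeLines(c(
    "@SQ\tSN:ctg1\tLN:10000",
    paste("r1", 16, "ctg1", 501, 60, "100S400M", "*", 0, 0,
          strrep("A", 500), "*", "NM:i:10", sep = "\t"),
    paste("r2", 4, "*", 0, 0, "*", "*", 0, 0, "ACGT", "*", sep = "\t")
  ), sam)
  aln <- read_sam(sam)
  expect_identical(nrow(aln), 1L)  # unmapped r2 dropped
  expect_identical(aln$strand, "-")
  # SAM-orientation interval [100,500) flips to [0,400) on the read itself
  expect_identical(aln$read_start, 0)
  expect_identical(aln$read_end, 400)
  expect_identical(aln$contig_start, 500)
  expect_identical(aln$contig_end, 900)
  expect_identical(aln$matched_bases, 390)
})

test_that("a non-read-grouped stream is rejected", {
  aln <- tibble(read_name = c("a", "b", "a")) |>
    dplyr::mutate(read_length = 1000, read_start = 0, read_end = 500,
                  strand = "+", contig = "c", contig_length = 1000,
                  contig_start = 0, contig_end = 500,
                  matched_bases = 450, aln_len = 500, mapq = 60)
  expect_error(alignment_batches(aln), "not grouped")
  expect_length(alignment_batches(aln[1:2, ]), 2L)
})

test_that("frames extrapolate the full contig extent onto the read", {
  mk <- function(rs, re, strand, cs, ce, L) tibble(
    read_name = "r", read_length = 5000, read_start = rs, read_end = re,
    strand = strand, contig = "c", contig_length = L,
    contig_start = cs, contig_end = ce, matched_bases = re - rs,
    aln_len = re - rs, mapq = 60)
  f1 <- compute_frames(mk(0, 5000, "+", 0, 5000, 5000))
  expect_identical(c(f1$frame_start, f1$frame_end), c(0, 5000))
  f2 <- compute_frames(mk(1000, 4000, "+", 2000, 5000, 10000))
  expect_identical(c(f2$frame_start, f2$frame_end), c(-1000, 9000))
  f3 <- compute_frames(mk(0, 3000, "-", 7000, 10000, 10000))
  expect_identical(c(f3$frame_start, f3$frame_end), c(0, 10000))
})

test_that("frame projection round-trips contig coordinates for both strands", {
  set.seed(11)
  for (i in 1:1000) {
    L <- sample(2000:50000, 1)
    cs <- sample(0:(L - 500), 1)
    ce <- sample((cs + 100):L, 1)
    rs <- sample(0:2000, 1)
    re <- rs + (ce - cs)
    strand <- sample(c("+", "-"), 1)
    aln <- tibble(read_name = "r", read_length = re + 100,
                  read_start = rs, read_end = re, strand = strand,
                  contig = "c", contig_length = L, contig_start = cs,
                  contig_end = ce, matched_bases = re - rs,
                  aln_len = re - rs, mapq = 60)
    f <- compute_frames(aln)
    # invert the projection
    if (strand == "+") {
      expect_identical(rs - f$frame_start, cs)
      expect_identical(rs - f$frame_start + (re - rs), ce)
    } else {
      expect_identical(L - (rs - f$frame_start), ce)
      expect_identical(L - (rs - f$frame_start) - (re - rs), cs)
    }
    expect_equal(as.numeric(f$frame_end - f$frame_start), as.numeric(L))
  }
})

test_that("adjacent unique-contig frames become placements with implied gaps", {
  frames <- tibble(
    read_name = "r", read_length = 50000,
    contig = c("A", "B"), orientation = "+",
    frame_start = c(-25000, 6000), frame_end = c(5000, 46000),
    identity = c(0.9, 0.85), anchor_span = c(5000, 6000))
  pl <- spanning_pairs(frames, c("A", "B"))
  expect_identical(nrow(pl), 1L)
  expect_setequal(c(pl$end1, pl$end2), c("A:tail", "B:head"))
  expect_identical(pl$gap, 1000)
  expect_identical(pl$quality, 0.85)

  expect_identical(nrow(spanning_pairs(frames[1, ], c("A", "B"))), 0L)
  # overlap: still emitted with negative gap
  frames2 <- dplyr::mutate(frames, frame_start = c(-23000, 6500),
                           frame_end = c(7000, 46500))
  expect_identical(spanning_pairs(frames2, c("A", "B"))$gap, -500)
  # anchor and identity filters apply
  weak <- dplyr::mutate(frames, identity = c(0.5, 0.85))
  expect_identical(nrow(spanning_pairs(weak, c("A", "B"))), 0L)
  expect_identical(nrow(spanning_pairs(frames, "A")), 0L)
})

test_that("placements accrete into bridges by gap consistency", {
  pl1 <- tibble(end1 = "A:tail", end2 = "B:head", gap = 1000,
                quality = 0.9, read_name = "r1", gap_seq = NA_character_)
  b <- accrete(new_bridge_set(), pl1)
  expect_identical(nrow(b), 1L)
  expect_identical(b$consensus_gap, 1000)
  expect_identical(b$n_supports, 1L)
  expect_identical(b$score, 0.9)

  # within max(200, 0.2*1000) = 200 of the consensus: same bridge
  pl2 <- dplyr::mutate(pl1, gap = 1150, read_name = "r2")
  b2 <- accrete(b, pl2)
  expect_identical(nrow(b2), 1L)
  expect_identical(b2$n_supports, 2L)
  expect_identical(b2$consensus_gap, weighted_median(c(1000, 1150), c(.9, .9)))

  # far outside tolerance: a second (contradicting) bridge on the same ends
  pl3 <- dplyr::mutate(pl1, gap = 8000, read_name = "r3")
  b3 <- accrete(b2, pl3)
  expect_identical(nrow(b3), 2L)

  expect_identical(score_bridge(NULL), 0)
  expect_equal(score_bridge(tibble(quality = c(0.85, 0.85))), 1.7)
})

test_that("accretion is invariant to placement endpoint order", {
  set.seed(23)
  pls <- tibble(
    end1 = sample(c("A:tail", "B:head"), 20, TRUE),
    gap = sample(c(500, 5000), 20, TRUE) + round(rnorm(20, 0, 50)),
    quality = runif(20, 0.7, 1),
    read_name = paste0("r", 1:20), gap_seq = NA_character_) |>
    dplyr::mutate(end2 = ifelse(end1 == "A:tail", "B:head", "A:tail"))
  # canonicalize as spanning_pairs would
  canon <- dplyr::mutate(pls,
    e1 = pmin(end1, end2), e2 = pmax(end1, end2), end1 = e1, end2 = e2) |>
    dplyr::select(end1, end2, gap, quality, read_name, gap_seq)
  b1 <- accrete(new_bridge_set(), canon)
  b2 <- accrete(new_bridge_set(), canon[sample(20), ])
  expect_identical(dplyr::arrange(b1, consensus_gap)$n_supports,
                   dplyr::arrange(b2, consensus_gap)$n_supports)
  expect_setequal(b1$end1, b2$end1)
})
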