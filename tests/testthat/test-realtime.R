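test_that("a zero-read stream leaves the assembly untouched", {
  ct <- make_classified(c("A", "B"), c(5000, 4000))
  res <- run_streaming(ct, longscaff:::empty_alignments())
  expect_identical(nrow(res$timeline), 0L)
  expect_setequal(unname(res$assembly$sequences), ct$sequence)
  expect_false(res$stopped_early)
})

test_that("alignments to unknown contigs are a hard error naming them", {
  ct <- make_classified("A", 5000)
  aln <- tibble(read_name = "r", read_length = 1000, read_start = 0,
                read_end = 500, strand = "+", contig = "GHOST",
                contig_length = 900, contig_start = 0, contig_end = 500,
                matched_bases = 450, aln_len = 500, mapq = 60)
  expect_error(run_streaming(ct, aln), "GHOST")
})

test_that("stop conditions: target count, all-circular, stalled layout", {
  tl <- tibble(timestamp = 1:3, bases_received = c(1e6, 2e6, 3e6),
               reads_received = c(100, 200, 300),
               n_sequences = c(5L, 3L, 2L), n50 = c(1e5, 2e5, 3e5),
               n_circular = c(0L, 1L, 2L))
  expect_identical(stop_condition(tl, list(target_n_sequences = 2)), "stop")
  expect_identical(stop_condition(tl, list(target_n_sequences = 1)),
                   "continue")
  expect_identical(stop_condition(tl, list(stop_all_circular = TRUE)), "stop")
  expect_identical(stop_condition(tl[1:2, ], list(stop_all_circular = TRUE)),
                   "continue")

  flat <- tibble(timestamp = 1:60, bases_received = cumsum(rep(1e5, 60)),
                 reads_received = 1:60 * 10, n_sequences = 4L, n50 = 2e5,
                 n_circular = 1L)
  expect_identical(stop_condition(flat), "stop")
  wobble <- dplyr::mutate(flat, n50 = 2e5 + (timestamp %% 7))
  expect_identical(stop_condition(wobble), "continue")
  expect_identical(stop_condition(flat[1:40, ]), "continue")
})

test_that("feature lift-over follows placement offset and orientation", {
  ct <- make_classified(c("A", "C"), c(10000, 5000))
  feats <- tibble(contig = c("A", "C"), start = c(10, 100),
                  end = c(200, 400), name = c("f_plain", "f_rev"),
                  strand = "+")
  # unmerged, unflagged contig: placement is the input interval
  st0 <- new_scaffold_state(ct)
  pf0 <- place_features(feats, st0)
  expect_identical(pf0$scaffold_start, c(10, 100))
  expect_identical(unique(pf0$replicon_status), "unassigned")

  # C placed in reverse at scaffold offset 10000 (A 10 kb + no gap):
  # feature [100,400) on a 5 kb contig lands at [14600,14900), flipped
  st <- merge_contigs(st0, make_bridge(1L, "A:tail", "C:tail", 0, score = 2))
  pf <- place_features(feats, st)
  frev <- pf[pf$name == "f_rev", ]
  expect_identical(frev$scaffold_start, 14600)
  expect_identical(frev$scaffold_end, 14900)
  expect_identical(frev$scaffold_strand, "-")

  # plasmid flag propagates to every feature of the component
  pf2 <- place_features(feats, st, plasmid_flags = "A")
  expect_identical(unique(pf2$replicon_status), "plasmid")

  expect_warning(
    place_features(dplyr::mutate(feats, contig = c("A", "NOPE")), st0),
    "NOPE")
})

test_that("feature status upgrades to circular_plasmid and is logged with bases", {
  run <- reference_run(7)
  plasmid_contig <- run$frag$truth$placements$contig[
    run$frag$truth$placements$replicon == "plasmid_1"]
  feats <- tibble(contig = plasmid_contig[1], start = 100, end = 400,
                  name = "amr_gene", strand = "+")
  res <- run_streaming(run$contigs, run$paf, features = feats,
                       plasmid_flags = plasmid_contig[1])
  expect_identical(res$features$replicon_status, "circular_plasmid")
  ev <- res$feature_events[res$feature_events$name == "amr_gene", ]
  expect_gt(nrow(ev), 0)
  expect_true(all(ev$bases_received <= max(res$timeline$bases_received)))
})

test_that("streaming runs are deterministic and internally consistent", {
  run <- reference_run(7)
  res <- run$res
  # final report equals statistics of the materialized assembly
  lens <- nchar(res$assembly$sequences)
  st <- compute_stats(lens)
  last <- res$timeline[nrow(res$timeline), ]
  expect_identical(last$n50, st$n50)
  expect_identical(last$n_sequences, st$n_sequences)

  res2 <- run_streaming(run$contigs, run$paf,
                        reads = setNames(run$reads$sequence,
                                         run$reads$read_name))
  expect_identical(res2$timeline, res$timeline)
  expect_identical(res2$assembly$sequences, res$assembly$sequences)
  expect_identical(res2$decisions, res$decisions)
})

test_that("timelines are monotone: bases increase, joins only break on logged events", {
  run <- reference_run(7)
  tl <- run$res$timeline
  expect_true(all(diff(tl$bases_received) > 0))
  dec <- run$res$decisions
  break_batches <- dec$batch[dec$event == "break"]
  up <- which(diff(tl$n_sequences) > 0) + 1  # batches where count rose
  expect_true(all(tl$timestamp[up] %in% break_batches))
  expect_true(all(diff(tl$n_circular) >= 0 |
                    (tl$timestamp[-1] %in% break_batches)))
})

test_that("the timeline autoplot builds", {
  run <- reference_run(7)
  p <- ggplot2::autoplot(as_timeline(run$res$timeline))
  expect_s3_class(p, "ggplot")
})
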