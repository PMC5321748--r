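test_that("genome simulation is a pure function of config and seed", {
  g1 <- simulate_genome(chrom_len = 50000,
                        repeats = list(list(length = 2000, copies = 3)),
                        plasmids = list(list(length = 8000, circular = TRUE)),
                        seed = 7)
  g2 <- simulate_genome(chrom_len = 50000,
                        repeats = list(list(length = 2000, copies = 3)),
                        plasmids = list(list(length = 8000, circular = TRUE)),
                        seed = 7)
  expect_identical(g1, g2)
  g3 <- simulate_genome(chrom_len = 50000,
                        repeats = list(list(length = 2000, copies = 3)),
                        seed = 8)
  expect_false(identical(g1$replicons$sequence[1], g3$replicons$sequence[1]))
  expect_true(g1$replicons$circular[g1$replicons$name == "plasmid_1"])
})

test_that("planted repeat copies are byte-identical and match the annotation", {
  g <- simulate_genome(chrom_len = 60000,
                       repeats = list(list(length = 3000, copies = 3)),
                       plasmids = list(), mutation_rate = 0, seed = 3)
  ann <- g$repeat_annotation
  chrom <- g$replicons$sequence[1]
  copies <- vapply(seq_len(nrow(ann)), function(i)
    substr(chrom, ann$start[i] + 1, ann$end[i]), character(1))
  expect_identical(length(unique(copies)), 1L)
  expect_identical(nchar(copies[1]), 3000L)
  # loci do not overlap
  o <- order(ann$start)
  expect_true(all(ann$start[o][-1] >= ann$end[o][-length(o)]))
})

test_that("fragmentation yields the combinatorial contig structure", {
  # no repeats: contigs are the replicons, no adjacencies except the
  # circular self-join
  g0 <- simulate_genome(chrom_len = 30000, repeats = list(),
                        plasmids = list(list(length = 9000, circular = TRUE)),
                        seed = 5)
  f0 <- fragment_assembly(g0, base_depth = 50, seed = 5)
  expect_identical(nrow(f0$contigs), 2L)
  expect_identical(nrow(f0$truth$adjacencies), 1L)  # plasmid self-join

  # linear chromosome with k repeat loci: k+1 unique contigs + 1 collapsed
  # repeat contig (+ plasmid)
  g <- simulate_genome(chrom_len = 100000,
                       repeats = list(list(length = 5000, copies = 3)),
                       plasmids = list(list(length = 15000, circular = TRUE)),
                       seed = 7)
  f <- fragment_assembly(g, base_depth = 60, seed = 7)
  expect_identical(nrow(f$contigs), 6L)  # 4 unique + 1 repeat + 1 plasmid
  expect_identical(nrow(f$truth$adjacencies), 4L)  # 3 chrom joins + self
  # true gaps between chromosome segments equal the repeat length
  chrom_adj <- f$truth$adjacencies[f$truth$adjacencies$gap > 0, ]
  expect_true(all(chrom_adj$gap == 5000))
})

test_that("collapsed repeat depth is centred at copy-number times base depth", {
  set.seed(99)
  reps <- vapply(1:40, function(s) {
    g <- simulate_genome(chrom_len = 100000,
                         repeats = list(list(length = 5000, copies = 3)),
                         plasmids = list(), seed = s)
    f <- fragment_assembly(g, base_depth = 60, noise_cv = 0.07, seed = s)
    max(f$contigs$depth)  # the collapsed repeat is the deepest contig
  }, numeric(1))
  expect_equal(mean(reps), 180, tolerance = 0.05)
  expect_gt(stats::sd(reps), 0)
})

test_that("error-free reads are exact oriented substrings of their replicon", {
  g <- simulate_genome(chrom_len = 40000, repeats = list(),
                       plasmids = list(list(length = 10000, circular = TRUE)),
                       seed = 13)
  rd <- simulate_long_reads(g, coverage = 3, sub = 0, ins = 0, del = 0,
                            seed = 13)
  seqs <- setNames(g$replicons$sequence, g$replicons$name)
  doubled <- setNames(paste0(seqs, seqs), names(seqs))  # wrap lookup
  for (i in seq_len(nrow(rd))) {
    r <- rd[i, ]
    s <- if (r$strand == "-") revcomp(r$sequence) else r$sequence
    expect_identical(substr(doubled[[r$replicon]], r$start + 1,
                            r$start + nchar(s)), s)
  }
})

test_that("simulated coverage and read count follow sampling theory", {
  g <- simulate_genome(chrom_len = 80000, repeats = list(),
                       plasmids = list(), seed = 2)
  rd <- simulate_long_reads(g, coverage = 10, median_len = 4000, seed = 2)
  bases <- sum(nchar(rd$sequence))
  expect_gt(bases, 10 * 80000)            # target reached ...
  expect_lt(bases, 10 * 80000 * 1.02)     # ... within 2% overshoot
  expect_identical(rd, simulate_long_reads(g, coverage = 10,
                                           median_len = 4000, seed = 2))
})

test_that("evaluation scores perfect, swapped, and missing adjacencies", {
  run <- reference_run(7)
  ev <- evaluate_assembly(run$res, run$frag$truth)
  expect_identical(ev$false_joins + ev$missed_joins, 0L)

  # deliberately swap one adjacency in the truth: exactly 1 false + 1 missed
  tr <- run$frag$truth
  broken <- tr
  broken$adjacencies$end1[1] <- longscaff:::other_port(
    broken$adjacencies$end1[1])
  ev2 <- evaluate_assembly(run$res, broken)
  expect_identical(ev2$false_joins, 1L)
  expect_identical(ev2$missed_joins, 1L)
})
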