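suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

# Build an in-memory contig tibble from (name, length-or-sequence, depth)
# triples. Sequences default to deterministic arbitrary DNA of the given
# length.
make_contigs <- function(names, lengths = NULL, depths, sequences = NULL,
                         seed = 42) {
  set.seed(seed)
  if (is.null(sequences)) {
    sequences <- vapply(lengths, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1))
  }
  tibble(
    id = seq_along(names), name = names, sequence = sequences,
    length = nchar(sequences), depth = depths,
    multiplicity = NA_integer_, is_unique = NA
  ) |>
    arrange(desc(length), name) |>
    mutate(id = row_number())
}

# Classified contigs (every contig unique unless flagged)
make_classified <- function(names, lengths, repeat_names = character(),
                            seed = 42) {
  make_contigs(names, lengths, depths = rep(50, length(names)),
               seed = seed) |>
    mutate(is_unique = !(name %in% repeat_names),
           multiplicity = ifelse(is_unique, 1L, 3L))
}

# A one-row bridge tibble as accrete() would produce it
make_bridge <- function(id, end1, end2, gap, score = 1, n = 1L,
                        gap_seq = NA_character_) {
  tibble(
    bridge_id = id, end1 = end1, end2 = end2, consensus_gap = gap,
    score = score, n_supports = n, committed = FALSE,
    supports = list(tibble(read_name = paste0("r", id), gap = gap,
                           quality = score / n, gap_seq = gap_seq)),
    fill = list(NULL)
  )
}

# Full reference scenario: 100 kb chromosome, 5 kb repeat x 3, 15 kb
# circular plasmid; reads median 8 kb at 12% error, 25x. Cached per seed so
# several tests can share a run.
.ref_cache <- new.env(parent = emptyenv())
reference_run <- function(seed) {
  key <- as.character(seed)
  if (!is.null(.ref_cache[[key]])) return(.ref_cache[[key]])
  g <- simulate_genome(chrom_len = 100000,
                       repeats = list(list(length = 5000, copies = 3)),
                       plasmids = list(list(length = 15000, circular = TRUE)),
                       seed = seed)
  fa <- fragment_assembly(g, base_depth = 60, noise_cv = 0.07, seed = seed)
  ct <- classify_contigs(fa$contigs, estimate_genome_depth(fa$contigs))
  reads <- simulate_long_reads(g, coverage = 25, median_len = 8000,
                               sub = 0.05, ins = 0.03, del = 0.04,
                               seed = seed)
  fq <- tempfile(fileext = ".fq"); fa_path <- tempfile(fileext = ".fa")
  write_fastq(reads, fq)
  write_contigs_fasta(ct, fa_path)
  paf <- align_long_reads(fq, fa_path)
  res <- run_streaming(ct, paf, reads = fq)
  out <- list(genome = g, frag = fa, contigs = ct, reads = reads,
              paf = paf, res = res)
  .ref_cache[[key]] <- out
  out
}
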