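#' Simulate a multi-replicon genome with interspersed repeats
#'
#' Generates an i.i.d. uniform-background chromosome with identical (or
#' lightly mutated) repeat copies planted at non-overlapping loci separated
#' by at least `min_spacing`, plus optional extra replicons (plasmids),
#' flagged circular. This is the genome structure that defeats short-read
#' assembly: contigs fragment at repeat boundaries and repeat copies
#' collapse onto a single contig.
#'
#' @param chrom_len chromosome length in bases (default 100000).
#' @param repeats list of repeat families, each `list(length=, copies=)`;
#'   copies >= 2 are planted on the chromosome.
#' @param plasmids list of `list(length=, circular=)` replicons.
#' @param mutation_rate per-base substitution rate between repeat copies
#'   (default 0 = byte-identical copies).
#' @param min_spacing minimum unique sequence between planted repeats and
#'   chromosome ends (default 8000 bases, comfortably above the spanning
#'   anchor requirement).
#' @param seed integer seed; the generator is a pure function of
#'   (config, seed).
#' @return list: `replicons` tibble (`name`, `sequence`, `length`,
#'   `circular`) and `repeat_annotation` tibble (`replicon`, `family`,
#'   `copy`, `start`, `end`).
#' @export
simulate_genome <- function(chrom_len = 100000,
                            repeats = list(list(length = 5000, copies = 3)),
                            plasmids = list(list(length = 15000,
                                                 circular = TRUE)),
                            mutation_rate = 0, min_spacing = 8000,
                            seed = 1) {
  set.seed(seed)
  items <- bind_rows(imap(repeats, function(r, fi) {
    stopifnot(r$copies >= 2)
    tibble(family = paste0("repeat_", fi), copy = seq_len(r$copies),
           length = r$length)
  }))
  k <- nrow(items)
  ann <- tibble(replicon = character(), family = character(),
                copy = integer(), start = numeric(), end = numeric())
  if (k > 0) {
    items <- items[sample(k), ]
    free <- chrom_len - sum(items$length) - (k + 1) * min_spacing
    if (free < 0) abort("infeasible repeat packing: chromosome too short")
    cuts <- sort(stats::runif(k))
    extra <- diff(c(0, cuts, 1)) * free
    pos <- numeric(k); at <- 0
    for (i in seq_len(k)) {
      at <- at + min_spacing + extra[i]
      pos[i] <- at
      at <- at + items$length[i]
    }
    ann <- mutate(items, replicon = "chromosome", start = round(pos),
                  end = round(pos) + .data$length) |>
      select("replicon", "family", "copy", "start", "end")
  }

  fam_seqs <- stats::setNames(
    map_chr(unique(ann$family), function(f)
      random_dna(items$length[items$family == f][1])),
    unique(ann$family))

  chrom <- strsplit(random_dna(chrom_len), "")[[1]]
  for (i in seq_len(nrow(ann))) {
    s <- fam_seqs[[ann$family[i]]]
    if (mutation_rate > 0) s <- point_mutate(s, mutation_rate)
    chrom[(ann$start[i] + 1):ann$end[i]] <- strsplit(s, "")[[1]]
  }

  reps <- tibble(name = "chromosome",
                 sequence = paste(chrom, collapse = ""),
                 circular = FALSE)
  for (pi in seq_along(plasmids)) {
    p <- plasmids[[pi]]
    reps <- add_row(reps, name = paste0("plasmid_", pi),
                    sequence = random_dna(p$length),
                    circular = isTRUE(p$circular))
  }
  reps$length <- nchar(reps$sequence)
  list(replicons = select(reps, "name", "sequence", "length", "circular"),
       repeat_annotation = ann)
}

point_mutate <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(ch)) < rate
  if (any(hit)) {
    bases <- c("A", "C", "G", "T")
    idx <- match(ch[hit], bases)
    ch[hit] <- bases[((idx + sample(1:3, sum(hit), replace = TRUE) - 1) %% 4) + 1]
  }
  paste(ch, collapse = "")
}

#' Fragment a simulated genome into a depth-annotated "short-read assembly"
#'
#' Splits every replicon at its planted repeat copies: inter-repeat
#' segments become unique contigs with depth drawn from
#' Normal(lambda, (noise_cv*lambda)^2) truncated positive, and each repeat
#' family collapses onto one contig with depth from
#' Normal(k*lambda, (noise_cv*k*lambda)^2), k the family's total copy
#' number — the collapsed-repeat depth inflation the copy-number classifier
#' exploits. Circular replicons merge their wrap-around segment. Contigs
#' are named in SPAdes dialect.
#'
#' @param genome result of [simulate_genome()].
#' @param base_depth lambda, single-copy short-read depth (default 60).
#' @param noise_cv coefficient of variation of depth noise (default 0.07).
#' @param seed integer seed.
#' @return list: `contigs` tibble (schema of [read_contigs()], unclassified)
#'   and `truth` list with `placements` and `adjacencies` (canonical
#'   oriented unique-contig end pairs with true gap).
#' @export
fragment_assembly <- function(genome, base_depth = 60, noise_cv = 0.07,
                              seed = 1) {
  set.seed(seed)
  ann <- genome$repeat_annotation
  segs <- list(); placements <- list(); adjacencies <- list()

  fam_copies <- ann |> count(.data$family, name = "k")

  for (ri in seq_len(nrow(genome$replicons))) {
    rep_row <- genome$replicons[ri, ]
    a <- ann |> filter(.data$replicon == rep_row$name) |>
      arrange(.data$start)
    L <- rep_row$length
    if (nrow(a) == 0) {
      segs[[length(segs) + 1]] <- tibble(
        replicon = rep_row$name, start = 0, end = L,
        kind = "unique", self_circular = rep_row$circular)
      next
    }
    bounds <- tibble(s = c(0, a$end), e = c(a$start, L))
    if (rep_row$circular) {
      # wrap-around: last segment joins the first across the origin
      wrap_seq_len <- (L - a$end[nrow(a)]) + a$start[1]
      segs[[length(segs) + 1]] <- tibble(
        replicon = rep_row$name, start = a$end[nrow(a)], end = L + a$start[1],
        kind = "unique_wrap", self_circular = FALSE)
      mid <- bounds[-c(1, nrow(bounds)), ]
      if (nrow(mid) > 0) {
        segs[[length(segs) + 1]] <- tibble(
          replicon = rep_row$name, start = mid$s, end = mid$e,
          kind = "unique", self_circular = FALSE)
      }
    } else {
      segs[[length(segs) + 1]] <- tibble(
        replicon = rep_row$name, start = bounds$s, end = bounds$e,
        kind = "unique", self_circular = FALSE)
    }
  }
  segs <- bind_rows(segs) |> filter(.data$end > .data$start)

  rep_seq <- stats::setNames(genome$replicons$sequence,
                             genome$replicons$name)
  seg_seq <- map_chr(seq_len(nrow(segs)), function(i) {
    s <- segs[i, ]
    L <- nchar(rep_seq[[s$replicon]])
    if (s$end <= L) substr(rep_seq[[s$replicon]], s$start + 1, s$end)
    else paste0(substr(rep_seq[[s$replicon]], s$start + 1, L),
                substr(rep_seq[[s$replicon]], 1, s$end - L))
  })

  draw_depth <- function(mu, cv) {
    repeat {
      d <- stats::rnorm(1, mu, cv * mu)
      if (d > 0) return(d)
    }
  }

  contig_rows <- tibble(
    sequence = seg_seq,
    depth = map_dbl(seg_seq, ~ draw_depth(base_depth, noise_cv)),
    truth_key = paste0("seg_", seq_along(seg_seq))
  )
  fam_first <- ann |> group_by(.data$family) |> slice_min(.data$copy) |>
    ungroup()
  for (i in seq_len(nrow(fam_first))) {
    f <- fam_first[i, ]
    k <- fam_copies$k[fam_copies$family == f$family]
    contig_rows <- add_row(
      contig_rows,
      sequence = substr(rep_seq[[f$replicon]], f$start + 1, f$end),
      depth = draw_depth(k * base_depth, noise_cv),
      truth_key = f$family)
  }

  contig_rows <- contig_rows |>
    mutate(length = nchar(.data$sequence)) |>
    arrange(desc(.data$length), .data$truth_key) |>
    mutate(name = paste0("NODE_", row_number()))
  key2name <- stats::setNames(contig_rows$name, contig_rows$truth_key)

  contigs <- contig_rows |>
    mutate(id = row_number(), multiplicity = NA_integer_, is_unique = NA) |>
    select("id", "name", "sequence", "length", "depth",
           "multiplicity", "is_unique")

  # truth: placements + adjacencies between consecutive unique segments
  segs$contig <- key2name[paste0("seg_", seq_len(nrow(segs)))]
  placements <- segs |>
    transmute(contig = .data$contig, replicon = .data$replicon,
              start = .data$start, end = .data$end, strand = "+",
              copy_number = 1L)
  adj <- list()
  for (rn in unique(segs$replicon)) {
    s <- segs |> filter(.data$replicon == rn) |> arrange(.data$start)
    circular <- genome$replicons$circular[genome$replicons$name == rn]
    if (nrow(s) == 1 && s$self_circular[1]) {
      adj[[length(adj) + 1]] <- canonical_adjacency(
        s$contig[1], s$contig[1], 0)
      next
    }
    if (nrow(s) > 1) {
      for (i in seq_len(nrow(s) - 1)) {
        adj[[length(adj) + 1]] <- canonical_adjacency(
          s$contig[i], s$contig[i + 1], s$start[i + 1] - s$end[i])
      }
    }
    if (circular && nrow(s) > 1) {
      gap <- (nchar(rep_seq[[rn]]) - s$end[nrow(s)]) + s$start[1]
      adj[[length(adj) + 1]] <- canonical_adjacency(
        s$contig[nrow(s)], s$contig[1], gap)
    }
  }
  list(contigs = contigs,
       truth = list(placements = placements,
                    adjacencies = if (length(adj) > 0) bind_rows(adj) else
                      tibble(end1 = character(), end2 = character(),
                             gap = numeric())))
}

# oriented adjacency (left contig in + orientation precedes right contig
# in + orientation) as a canonical port pair
canonical_adjacency <- function(left, right, gap) {
  p1 <- port(left, "tail"); p2 <- port(right, "head")
  if (p1 > p2) { tmp <- p1; p1 <- p2; p2 <- tmp }
  tibble(end1 = p1, end2 = p2, gap = gap)
}

#' Simulate a stream of noisy long reads
#'
#' Reads are drawn uniformly over each replicon (proportionally to length,
#' wrapping across the origin of circular replicons), with log-normal
#' lengths and uniform per-base substitution/insertion/deletion noise, then
#' emitted in random order (modeling pore arrival) under the seed. Defaults
#' approximate early-chemistry nanopore data: median 8 kb reads, 5%
#' substitutions, 3% insertions, 4% deletions (12% total error).
#'
#' @param genome result of [simulate_genome()].
#' @param coverage target total bases as a multiple of genome length
#'   (default 25).
#' @param median_len median read length (default 8000); `sdlog` the
#'   log-normal spread (default 0.35).
#' @param sub,ins,del per-base error rates, each in \[0, 0.2\].
#' @param min_len shortest emitted read (default 500).
#' @param seed integer seed.
#' @return tibble in emission order: `read_name`, `sequence`, `replicon`,
#'   `start`, `end`, `strand`.
#' @export
simulate_long_reads <- function(genome, coverage = 25, median_len = 8000,
                                sdlog = 0.35, sub = 0.05, ins = 0.03,
                                del = 0.04, min_len = 500, seed = 1) {
  stopifnot(coverage > 0, all(c(sub, ins, del) >= 0),
            all(c(sub, ins, del) <= 0.2))
  set.seed(seed)
  reps <- genome$replicons
  target <- coverage * sum(reps$length)
  rows <- list(); total <- 0
  while (total < target) {
    ri <- sample.int(nrow(reps), 1, prob = reps$length)
    L <- reps$length[ri]
    len <- max(min_len, round(stats::rlnorm(1, log(median_len), sdlog)))
    start <- sample.int(L, 1) - 1
    if (reps$circular[ri]) {
      len <- min(len, L)
      end <- start + len
      raw <- if (end <= L) substr(reps$sequence[ri], start + 1, end)
             else paste0(substr(reps$sequence[ri], start + 1, L),
                         substr(reps$sequence[ri], 1, end - L))
    } else {
      end <- min(start + len, L)
      if (end - start < min_len) next
      raw <- substr(reps$sequence[ri], start + 1, end)
    }
    strand <- sample(c("+", "-"), 1)
    seq <- if (strand == "-") revcomp(raw) else raw
    seq <- apply_read_errors(seq, sub, ins, del)
    total <- total + nchar(seq)
    rows[[length(rows) + 1]] <- tibble(
      replicon = reps$name[ri], start = start, end = end, strand = strand,
      sequence = seq)
  }
  out <- bind_rows(rows)
  out <- out[sample.int(nrow(out)), ]
  out |>
    mutate(read_name = sprintf("read_%05d", row_number())) |>
    select("read_name", "sequence", "replicon", "start", "end", "strand")
}

apply_read_errors <- function(seq, sub, ins, del) {
  if (sub + ins + del == 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  op <- sample(c("M", "S", "I", "D"), n, replace = TRUE,
               prob = c(1 - sub - ins - del, sub, ins, del))
  bases <- c("A", "C", "G", "T")
  s_idx <- which(op == "S")
  if (length(s_idx) > 0) {
    cur <- match(ch[s_idx], bases)
    cur[is.na(cur)] <- 1L
    ch[s_idx] <- bases[((cur + sample(1:3, length(s_idx), TRUE) - 1) %% 4) + 1]
  }
  i_idx <- which(op == "I")
  if (length(i_idx) > 0) {
    ch[i_idx] <- paste0(ch[i_idx], sample(bases, length(i_idx), TRUE))
  }
  ch[op == "D"] <- ""
  paste(ch, collapse = "")
}

#' Write reads to FASTQ (flat quality)
#'
#' @param reads tibble from [simulate_long_reads()].
#' @param path output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  lines <- unlist(map(seq_len(nrow(reads)), function(i) {
    c(paste0("@", reads$read_name[i]), reads$sequence[i], "+",
      strrep("I", nchar(reads$sequence[i])))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Write contigs to FASTA with SPAdes-dialect headers
#'
#' @param contigs contig tibble.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_contigs_fasta <- function(contigs, path) {
  hdr <- sprintf("%s_length_%d_cov_%.6f", contigs$name, contigs$length,
                 contigs$depth)
  x <- Biostrings::DNAStringSet(stats::setNames(contigs$sequence, hdr))
  Biostrings::writeXStringSet(x, path, width = 80)
  invisible(path)
}

#' Align long reads to contigs with minimap2
#'
#' Thin wrapper over the external `minimap2` binary (`-c -x map-ont
#' --secondary=no`, one thread) producing base-level PAF alignments whose
#' residue-match counts feed the anchor-identity filter. The core consumes
#' alignments only; any streaming aligner producing PAF/SAM can substitute.
#'
#' @param reads_fastq path to reads (FASTQ/FASTA).
#' @param contigs_fasta path to the contig FASTA.
#' @param out optional output PAF path (default: tempfile).
#' @param extra_args additional minimap2 arguments.
#' @return path to the PAF file.
#' @export
align_long_reads <- function(reads_fastq, contigs_fasta, out = tempfile(fileext = ".paf"),
                             extra_args = character()) {
  if (Sys.which("minimap2") == "") {
    abort("minimap2 not found on PATH; supply alignments as PAF/SAM instead")
  }
  status <- system2("minimap2",
                    c("-c", "-x", "map-ont", "--secondary=no", "-t", "1",
                      extra_args, shQuote(contigs_fasta), shQuote(reads_fastq)),
                    stdout = out, stderr = FALSE)
  if (status != 0) abort("minimap2 failed")
  out
}

# strip SPAdes length/cov decorations so alignment target names match
# contig names
normalize_contig_names <- function(x) {
  sub("^(NODE_\\d+)_length_\\d+_cov_[0-9.eE+-]+$", "\\1", x)
}

#' Compare a scaffold layout with the simulated truth
#'
#' Joins are compared as canonical oriented adjacency pairs of unique
#' contig ends: a true join is a committed adjacency present in the truth
#' table, a false join is a committed adjacency absent from it, and a
#' missed join is a true adjacency the layout lacks.
#'
#' @param state a `scaffold_state` (or a result list from
#'   [run_streaming()], whose `$state` is used).
#' @param truth truth list from [fragment_assembly()].
#' @return tibble: `true_joins`, `false_joins`, `missed_joins`, plus the
#'   offending pairs in list-columns `false_pairs`, `missed_pairs`.
#' @export
evaluate_assembly <- function(state, truth) {
  if (!inherits(state, "scaffold_state") && !is.null(state$state)) {
    state <- state$state
  }
  lay <- scaffold_layout(state)
  found <- list()
  for (sc in unique(lay$scaffold)) {
    part <- filter(lay, .data$scaffold == sc)
    n <- nrow(part)
    seg_ports <- function(k, side) {
      ori <- part$orientation[k]
      if (side == "exit") port(part$contig[k], if (ori == "+") "tail" else "head")
      else port(part$contig[k], if (ori == "+") "head" else "tail")
    }
    if (n > 1) {
      for (k in seq_len(n - 1)) {
        p1 <- seg_ports(k, "exit"); p2 <- seg_ports(k + 1, "enter")
        found[[length(found) + 1]] <- sort_pair(p1, p2)
      }
    }
    if (part$circular[1]) {
      p1 <- seg_ports(n, "exit"); p2 <- seg_ports(1, "enter")
      found[[length(found) + 1]] <- sort_pair(p1, p2)
    }
  }
  found_keys <- unique(map_chr(found, ~ paste(.x, collapse = "|")))
  truth_keys <- paste(truth$adjacencies$end1, truth$adjacencies$end2,
                      sep = "|")
  tibble(
    true_joins = sum(found_keys %in% truth_keys),
    false_joins = sum(!(found_keys %in% truth_keys)),
    missed_joins = sum(!(truth_keys %in% found_keys)),
    false_pairs = list(setdiff(found_keys, truth_keys)),
    missed_pairs = list(setdiff(truth_keys, found_keys))
  )
}

sort_pair <- function(p1, p2) if (p1 <= p2) c(p1, p2) else c(p2, p1)
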