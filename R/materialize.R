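#' Assembly statistics (sequence count and N50)
#'
#' N50 is the length of the shortest sequence in the smallest set of longest
#' sequences whose summed length reaches half the total. Sequences shorter
#' than `min_len` are excluded first, matching the common convention of
#' counting contigs of at least 500 bp.
#'
#' @param lengths numeric vector of sequence lengths in bases.
#' @param min_len minimum length to retain (default 500).
#' @return tibble with `n_sequences` and `n50`.
#' @export
compute_stats <- function(lengths, min_len = 500) {
  keep <- lengths[lengths >= min_len]
  if (length(keep) == 0) {
    abort("no sequences remain after the minimum-length filter")
  }
  keep <- sort(keep, decreasing = TRUE)
  half <- sum(keep) / 2
  n50 <- keep[which(cumsum(keep) >= half)[1]]
  tibble(n_sequences = length(keep), n50 = n50)
}

oriented_seq <- function(seq, orientation) {
  if (orientation == "-") revcomp(seq) else seq
}

# Fill sequence for a committed bridge, oriented for a traversal that
# crosses it from `from_port`; fills are stored end1 -> end2.
bridge_fill_seq <- function(state, bid, from_port) {
  i <- match(bid, state$bridges$bridge_id)
  f <- state$bridges$fill[[i]]
  gap <- state$bridges$gap[i]
  seq <- if (!is.null(f)) f$sequence else strrep("N", max(0, round(gap)))
  src <- if (!is.null(f)) f$source else "n_gap"
  if (identical(state$bridges$end2[i], from_port) && nzchar(seq)) {
    seq <- revcomp(seq)
  }
  list(seq = seq, source = src)
}

#' Materialize the scaffold state into output sequences
#'
#' Emits one sequence per layout component: oriented contig sequences
#' interleaved with gap fills; negative gaps are trimmed from the start of
#' the incoming segment. Circular components additionally splice the
#' closing bridge's fill (or trim its overlap) without duplicating junction
#' bases, and are flagged. Repetitive contigs not consumed by any committed
#' gap fill are emitted as singletons under their own names. Scaffolds are
#' named `scaffold_<k>` by decreasing length, suffixed `_circular`.
#'
#' @param state a `scaffold_state`.
#' @param include_singletons emit unplaced repetitive contigs (default TRUE).
#' @return list with `sequences` (named character), `circular` (named
#'   logical), and `layout` (segment table with scaffold coordinates and
#'   segment kinds `unique` / `repeat_fill` / `raw_read_fill` / `n_gap`).
#' @export
materialize_assembly <- function(state, include_singletons = TRUE) {
  lay <- scaffold_layout(state)
  seqs <- character(); circ <- logical(); seg_rows <- list()
  contig_seq <- stats::setNames(state$contigs$sequence, state$contigs$name)

  for (sc in unique(lay$scaffold)) {
    part <- filter(lay, .data$scaffold == sc)
    nm <- part$scaffold_name[1]
    pieces <- character(); pos <- 0
    exit_port <- NULL
    for (k in seq_len(nrow(part))) {
      seg <- part[k, ]
      sseq <- oriented_seq(contig_seq[[seg$contig]], seg$orientation)
      if (k > 1) {
        g <- seg$gap_before
        enter_port <- port(seg$contig,
                           if (seg$orientation == "+") "head" else "tail")
        if (g > 0) {
          f <- bridge_fill_seq(state, seg$bridge_in, from_port = exit_port)
          if (nzchar(f$seq)) {
            seg_rows[[length(seg_rows) + 1]] <- tibble(
              scaffold_name = nm, start = pos, end = pos + nchar(f$seq),
              contig = NA_character_, orientation = "+",
              kind = switch(f$source, repeat_contig = "repeat_fill",
                            raw_read = "raw_read_fill", "n_gap"))
            pieces <- c(pieces, f$seq); pos <- pos + nchar(f$seq)
          }
        } else if (g < 0) {
          sseq <- substr(sseq, -g + 1, nchar(sseq))  # trim overlap
        }
      }
      seg_rows[[length(seg_rows) + 1]] <- tibble(
        scaffold_name = nm, start = pos, end = pos + nchar(sseq),
        contig = seg$contig, orientation = seg$orientation, kind = "unique")
      pieces <- c(pieces, sseq); pos <- pos + nchar(sseq)
      exit_port <- port(seg$contig,
                        if (seg$orientation == "+") "tail" else "head")
    }
    out <- paste(pieces, collapse = "")
    if (part$circular[1]) {
      g <- part$closing_gap[1]
      if (!is.na(g) && g > 0) {
        f <- bridge_fill_seq(state, part$closing_bridge[1],
                             from_port = exit_port)
        if (nzchar(f$seq)) {
          seg_rows[[length(seg_rows) + 1]] <- tibble(
            scaffold_name = nm, start = pos, end = pos + nchar(f$seq),
            contig = NA_character_, orientation = "+",
            kind = switch(f$source, repeat_contig = "repeat_fill",
                          raw_read = "raw_read_fill", "n_gap"))
          out <- paste0(out, f$seq)
        }
      } else if (!is.na(g) && g < 0) {
        out <- substr(out, 1, nchar(out) + g)  # trim junction overlap
      }
    }
    seqs[[nm]] <- out
    circ[[nm]] <- part$circular[1]
  }

  if (include_singletons) {
    used <- placed_repeats(state)
    reps <- filter(state$contigs, !.data$is_unique, !(.data$name %in% used))
    for (i in seq_len(nrow(reps))) {
      seqs[[reps$name[i]]] <- reps$sequence[i]
      circ[[reps$name[i]]] <- FALSE
      seg_rows[[length(seg_rows) + 1]] <- tibble(
        scaffold_name = reps$name[i], start = 0, end = reps$length[i],
        contig = reps$name[i], orientation = "+", kind = "repeat_singleton")
    }
  }

  # scaffolds first (already span-ordered by the layout), then singleton
  # repeats by decreasing length
  scaff <- names(seqs) %in% lay$scaffold_name
  ord <- order(!scaff, ifelse(scaff, match(names(seqs), lay$scaffold_name),
                              -nchar(seqs)), names(seqs))
  seqs <- seqs[ord]; circ <- circ[ord]
  layout <- bind_rows(seg_rows)

  list(sequences = seqs, circular = circ,
       layout = arrange(layout, match(.data$scaffold_name, names(seqs)),
                        .data$start))
}

#' Write assembly sequences to FASTA
#'
#' @param assembly result of [materialize_assembly()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_assembly_fasta <- function(assembly, path) {
  x <- Biostrings::DNAStringSet(assembly$sequences)
  Biostrings::writeXStringSet(x, path, width = 80)
  invisible(path)
}

#' Write the scaffold layout as AGP v2.1
#'
#' Unique contigs become `W` component lines; fills and gaps become `N` gap
#' lines (`scaffold` gap type, linked, `align_genus` evidence). Coordinates
#' are converted to the 1-based inclusive convention AGP requires.
#'
#' @param assembly result of [materialize_assembly()].
#' @param path output AGP path.
#' @return `path`, invisibly.
#' @export
write_agp <- function(assembly, path) {
  lines <- c("##agp-version\t2.1")
  for (nm in unique(assembly$layout$scaffold_name)) {
    part <- filter(assembly$layout, .data$scaffold_name == nm)
    for (k in seq_len(nrow(part))) {
      p <- part[k, ]
      if (p$kind %in% c("unique", "repeat_singleton")) {
        lines <- c(lines, paste(
          nm, p$start + 1, p$end, k, "W", p$contig, 1, p$end - p$start,
          p$orientation, sep = "\t"))
      } else {
        lines <- c(lines, paste(
          nm, p$start + 1, p$end, k, "N", p$end - p$start, "scaffold",
          "yes", "align_genus", sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a report timeline as JSON-lines (one object per batch)
#'
#' @param timeline report tibble ([run_streaming()] `timeline`).
#' @param path output `.jsonl` path.
#' @return `path`, invisibly.
#' @export
write_reports_jsonl <- function(timeline, path) {
  lines <- map_chr(seq_len(nrow(timeline)), function(i) {
    jsonlite::toJSON(as.list(timeline[i, ]), auto_unbox = TRUE, digits = NA)
  })
  writeLines(lines, path)
  invisible(path)
}
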