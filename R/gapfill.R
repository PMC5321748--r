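#' Fill the gap of a committed bridge
#'
#' A positive gap between two joined contig ends is first filled with the
#' spanning subsequence of the highest-quality supporting read (the
#' "backbone"). Repetitive contigs are then locally aligned against the
#' backbone and non-overlapping hits at identity >= `min_fill_identity`
#' replace the matched backbone segments with the (accurate, short-read
#' derived) contig bases; the rest of the backbone keeps raw-read sequence.
#' Gaps of zero or negative size need no fill — overlaps are trimmed at
#' materialization. When no support carries sequence (e.g. alignment-only
#' input), the gap is padded with `N`s of the consensus length.
#'
#' @param gap consensus gap in bases (signed).
#' @param supports support tibble of the bridge (`read_name`, `gap`,
#'   `quality`, `gap_seq`).
#' @param repeat_contigs tibble of repetitive contigs (`name`, `sequence`).
#' @param min_fill_identity minimum local-alignment identity for a repeat
#'   contig to replace backbone sequence (default 0.75).
#' @param min_hit_span minimum aligned span for a repeat hit (default 300).
#' @return a fill object: list with `source` (`raw_read`, `repeat_contig`,
#'   `n_gap`, or `none`), `sequence`, `donor`, and a `segments` tibble
#'   recording per-segment provenance.
#' @export
fill_gap <- function(gap, supports, repeat_contigs = NULL,
                     min_fill_identity = 0.75, min_hit_span = 300) {
  if (is.na(gap) || gap <= 0) {
    return(list(source = "none", sequence = "", donor = NA_character_,
                segments = fill_segments()))
  }
  sup <- supports
  backbone <- NULL; donor <- NA_character_
  if (!is.null(sup) && nrow(sup) > 0) {
    sup <- sup |> filter(!is.na(.data$gap_seq)) |> arrange(desc(.data$quality))
    if (nrow(sup) > 0) {
      backbone <- sup$gap_seq[1]
      donor <- sup$read_name[1]
    }
  }
  if (is.null(backbone) || !nzchar(backbone)) {
    return(list(
      source = "n_gap", donor = NA_character_,
      sequence = strrep("N", max(0, round(gap))),
      segments = fill_segments(0, max(0, round(gap)), "n_gap", NA_character_)
    ))
  }

  hits <- repeat_fill_hits(backbone, repeat_contigs,
                           min_fill_identity, min_hit_span)
  if (nrow(hits) == 0) {
    return(list(source = "raw_read", sequence = backbone, donor = donor,
                segments = fill_segments(0, nchar(backbone), "raw_read", donor)))
  }

  # rebuild left-to-right, splicing repeat bases over matched segments
  hits <- arrange(hits, .data$sstart)
  pieces <- character(); segs <- list(); pos <- 0
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    if (h$sstart > pos) {
      pieces <- c(pieces, substr(backbone, pos + 1, h$sstart))
      segs[[length(segs) + 1]] <- fill_segments(pos, h$sstart, "raw_read", donor)
    }
    pieces <- c(pieces, h$seq)
    segs[[length(segs) + 1]] <-
      fill_segments(h$sstart, h$send, "repeat_contig", h$contig, h$identity)
    pos <- h$send
  }
  if (pos < nchar(backbone)) {
    pieces <- c(pieces, substr(backbone, pos + 1, nchar(backbone)))
    segs[[length(segs) + 1]] <-
      fill_segments(pos, nchar(backbone), "raw_read", donor)
  }
  list(source = "repeat_contig", sequence = paste(pieces, collapse = ""),
       donor = hits$contig[1], segments = bind_rows(segs))
}

fill_segments <- function(start = numeric(), end = numeric(),
                          source = character(), donor = character(),
                          identity = rep(NA_real_, length(start))) {
  tibble(start = start, end = end, source = source,
         donor = donor, identity = identity)
}

# Local alignments of repeat contigs (both strands) against a backbone;
# greedy non-overlapping selection by alignment score.
repeat_fill_hits <- function(backbone, repeat_contigs,
                             min_fill_identity, min_hit_span) {
  empty <- tibble(contig = character(), sstart = numeric(), send = numeric(),
                  identity = numeric(), score = numeric(), seq = character())
  if (is.null(repeat_contigs) || nrow(repeat_contigs) == 0) return(empty)
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 2, mismatch = -3, baseOnly = FALSE)
  subject <- Biostrings::DNAString(backbone)
  cands <- list()
  for (i in seq_len(nrow(repeat_contigs))) {
    rc_name <- repeat_contigs$name[i]
    for (ori in c("+", "-")) {
      pat <- repeat_contigs$sequence[i]
      if (ori == "-") pat <- revcomp(pat)
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(pat), subject, type = "local",
        substitutionMatrix = submat, gapOpening = 5, gapExtension = 2)
      srange <- Biostrings::subject(aln)
      sstart <- Biostrings::start(srange) - 1
      send <- Biostrings::end(srange)
      ident <- Biostrings::pid(aln) / 100
      span <- send - sstart
      if (span >= min_hit_span && ident >= min_fill_identity) {
        matched <- as.character(Biostrings::alignedPattern(aln))
        matched <- gsub("-", "", matched, fixed = TRUE)
        cands[[length(cands) + 1]] <- tibble(
          contig = rc_name, sstart = sstart, send = send,
          identity = ident, score = Biostrings::score(aln), seq = matched)
      }
    }
  }
  if (length(cands) == 0) return(empty)
  cands <- bind_rows(cands) |> arrange(desc(.data$score))
  keep <- rep(FALSE, nrow(cands))
  for (i in seq_len(nrow(cands))) {
    ov <- keep & (cands$sstart < cands$send[i]) & (cands$send > cands$sstart[i])
    if (!any(ov)) keep[i] <- TRUE
  }
  cands[keep, ]
}

#' Compute (or refresh) gap fills for all committed bridges
#'
#' Fills are computed when a bridge is committed and refreshed when its
#' support set changes; uncommitting a bridge discards its fill, returning
#' any repeat contigs it used to the available pool (a repetitive contig
#' may legitimately serve several gaps — it represents a multi-copy
#' element).
#'
#' @param state a `scaffold_state`.
#' @param min_fill_identity see [fill_gap()].
#' @param only integer bridge ids to (re)fill; default: all with no fill.
#' @return the updated state.
#' @export
compute_fills <- function(state, min_fill_identity = 0.75, only = NULL) {
  reps <- filter(state$contigs, !.data$is_unique)
  idx <- seq_len(nrow(state$bridges))
  if (!is.null(only)) idx <- idx[state$bridges$bridge_id[idx] %in% only]
  for (i in idx) {
    if (is.null(only) && !is.null(state$bridges$fill[[i]])) next
    state$bridges$fill[[i]] <- fill_gap(
      state$bridges$gap[i], state$bridges$supports[[i]], reps,
      min_fill_identity = min_fill_identity)
  }
  state
}

# Names of repeat contigs consumed by committed fills.
placed_repeats <- function(state) {
  unique(unlist(map(state$bridges$fill, function(f) {
    if (is.null(f)) return(character())
    f$segments$donor[f$segments$source == "repeat_contig"]
  })))
}
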