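#' Read long-read-to-contig alignments from PAF
#'
#' Parses the 12 standard PAF columns into one row per alignment record.
#' Query coordinates are 0-based half-open in the original read orientation,
#' as PAF defines them. Extra SAM-style tags are ignored. Unparsable lines
#' are skipped with a warning tally.
#'
#' @param path PAF file path (`"-"` reads standard input).
#' @return alignment tibble: `read_name`, `read_length`, `read_start`,
#'   `read_end`, `strand`, `contig`, `contig_length`, `contig_start`,
#'   `contig_end`, `matched_bases`, `aln_len`, `mapq`.
#' @export
read_paf <- function(path) {
  con <- if (identical(path, "-")) file("stdin") else path
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_alignments())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(parts) >= 12
  if (any(!ok)) warn(sprintf("skipped %d unparsable PAF line(s)", sum(!ok)))
  parts <- parts[ok]
  if (length(parts) == 0) return(empty_alignments())
  col <- function(i) map_chr(parts, i)
  num <- function(i) as.numeric(col(i))
  tibble(
    read_name = col(1), read_length = num(2),
    read_start = num(3), read_end = num(4),
    strand = col(5),
    contig = col(6), contig_length = num(7),
    contig_start = num(8), contig_end = num(9),
    matched_bases = num(10), aln_len = num(11), mapq = num(12)
  )
}

empty_alignments <- function() {
  tibble(
    read_name = character(), read_length = numeric(),
    read_start = numeric(), read_end = numeric(), strand = character(),
    contig = character(), contig_length = numeric(),
    contig_start = numeric(), contig_end = numeric(),
    matched_bases = numeric(), aln_len = numeric(), mapq = numeric()
  )
}

# Walk a CIGAR string; returns per-record query/reference extents.
cigar_walk <- function(cigar) {
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  n <- as.numeric(sub("[MIDNSHP=X]$", "", toks))
  op <- sub("^\\d+", "", toks)
  qcons <- op %in% c("M", "I", "S", "=", "X")
  rcons <- op %in% c("M", "D", "N", "=", "X")
  clip <- op %in% c("S", "H")
  read_len <- sum(n[qcons | op == "H"])
  lead <- 0
  i <- 1
  while (i <= length(op) && clip[i]) { lead <- lead + n[i]; i <- i + 1 }
  trail <- 0
  i <- length(op)
  while (i >= 1 && clip[i]) { trail <- trail + n[i]; i <- i - 1 }
  list(read_len = read_len, lead = lead, trail = trail,
       ref_span = sum(n[rcons]), m_len = sum(n[op %in% c("M", "=", "X")]),
       block = sum(n[op %in% c("M", "I", "D", "=", "X")]))
}

#' Read long-read-to-contig alignments from SAM
#'
#' Parses a text SAM stream (header required for contig lengths). Unmapped
#' records are dropped; secondary and supplementary records are kept since
#' split alignments carry the bridging signal. Read coordinates are reported
#' in the original read orientation (reverse-strand records are flipped), so
#' downstream frame arithmetic is identical for SAM and PAF input.
#'
#' @param path SAM file path (`"-"` reads standard input).
#' @return alignment tibble with the same columns as [read_paf()].
#' @export
read_sam <- function(path) {
  con <- if (identical(path, "-")) file("stdin") else path
  lines <- readLines(con)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  sq <- hdr[startsWith(hdr, "@SQ")]
  sq_name <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  sq_len <- as.numeric(sub(".*\tLN:([^\t]+).*", "\\1", sq))
  if (length(body) == 0) return(empty_alignments())

  recs <- map(body, function(line) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) return(NULL)
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) > 0) return(NULL)  # unmapped
    cw <- cigar_walk(f[6])
    rev <- bitwAnd(flag, 16L) > 0
    read_len <- cw$read_len
    # clip-walk gives the interval in SAM orientation; flip for reverse
    rs <- if (rev) cw$trail else cw$lead
    re <- read_len - (if (rev) cw$lead else cw$trail)
    nm <- sub(".*\tNM:i:(\\d+).*", "\\1", line)
    nm <- if (nm == line) NA_real_ else as.numeric(nm)
    matched <- if (is.na(nm)) cw$m_len else max(0, cw$m_len - nm)
    tlen <- sq_len[match(f[3], sq_name)]
    tibble(
      read_name = f[1], read_length = read_len,
      read_start = rs, read_end = re,
      strand = if (rev) "-" else "+",
      contig = f[3], contig_length = tlen,
      contig_start = as.numeric(f[4]) - 1,
      contig_end = as.numeric(f[4]) - 1 + cw$ref_span,
      matched_bases = matched, aln_len = cw$block,
      mapq = as.numeric(f[5])
    )
  })
  out <- bind_rows(recs)
  if (nrow(out) == 0) return(empty_alignments())
  if (nrow(out) > 0 && anyNA(out$contig_length)) {
    abort("SAM header lacks @SQ lengths for some aligned contigs")
  }
  out
}

#' Group an alignment table into per-read batches in stream order
#'
#' Alignments arrive grouped by read (as a streaming aligner emits them);
#' this splits the table into one element per read, preserving first-seen
#' order. Detects and rejects streams that are not read-grouped.
#'
#' @param alignments tibble from [read_paf()] / [read_sam()].
#' @return named list of per-read alignment tibbles.
#' @export
alignment_batches <- function(alignments) {
  if (nrow(alignments) == 0) return(list())
  first_seen <- !duplicated(alignments$read_name)
  runs <- rle(alignments$read_name)
  if (anyDuplicated(runs$values) > 0) {
    abort("alignment stream is not grouped by read")
  }
  split(alignments, factor(alignments$read_name,
                           levels = alignments$read_name[first_seen]))
}

#' Project a contig's full extent into read coordinates
#'
#' Linearly extrapolates an alignment so the whole contig occupies an
#' interval on the read (possibly extending beyond the read's ends). Two
#' contigs framed on the same read expose their relative distance and
#' orientation directly as interval arithmetic.
#'
#' @param alignments one or more alignment rows.
#' @return frame tibble: `read_name`, `contig`, `orientation`,
#'   `frame_start`, `frame_end`, `identity`, `anchor_span`,
#'   plus read bookkeeping columns.
#' @export
compute_frames <- function(alignments) {
  alignments |>
    mutate(
      frame_start = ifelse(
        .data$strand == "+",
        .data$read_start - .data$contig_start,
        .data$read_start - (.data$contig_length - .data$contig_end)
      ),
      frame_end = .data$frame_start + .data$contig_length,
      orientation = .data$strand,
      identity = .data$matched_bases / pmax(1, .data$aln_len),
      anchor_span = .data$contig_end - .data$contig_start
    ) |>
    select("read_name", "read_length", "contig", "orientation",
           "frame_start", "frame_end", "identity", "anchor_span")
}

# Drop near-duplicate frames of the same contig (split/secondary alignments
# re-framing the same placement); keeps the higher-identity frame.
dedupe_frames <- function(frames) {
  if (nrow(frames) < 2) return(frames)
  frames <- arrange(frames, desc(.data$identity * .data$anchor_span))
  keep <- rep(TRUE, nrow(frames))
  for (i in seq_len(nrow(frames))[-1]) {
    for (j in seq_len(i - 1)) {
      if (!keep[j]) next
      if (frames$contig[i] != frames$contig[j]) next
      ov <- min(frames$frame_end[i], frames$frame_end[j]) -
        max(frames$frame_start[i], frames$frame_start[j])
      len <- frames$frame_end[i] - frames$frame_start[i]
      if (ov > 0.8 * len) { keep[i] <- FALSE; break }
    }
  }
  arrange(frames[keep, ], .data$frame_start, .data$frame_end, .data$contig)
}

#' Extract spanning placements of unique-contig pairs from one read
#'
#' Frames are filtered to well-anchored (`anchor_span >= min_anchor`,
#' `identity >= min_identity`) alignments to unique contigs, ordered along
#' the read, and each adjacent pair is emitted as a candidate placement:
#' an oriented pair of contig ends with an implied gap (negative = overlap).
#' Only adjacent pairs are emitted; longer-range joins emerge transitively.
#' A wrapping read on a circular replicon yields a placement joining the two
#' ends of the same contig.
#'
#' @param frames frame tibble for a single read ([compute_frames()]).
#' @param unique_contigs character vector of unique-contig names.
#' @param min_anchor minimum aligned span on the contig (default 300 bp).
#' @param min_identity minimum anchor identity (default 0.6).
#' @param read_seq optional read sequence (original orientation) used to
#'   extract the gap subsequence between the two anchors for gap filling.
#' @return placement tibble: canonical `end1`, `end2` ports (`contig:head` /
#'   `contig:tail`), `gap`, `quality`, `read_name`, `gap_seq` (NA when the
#'   read does not fully span a positive gap).
#' @export
spanning_pairs <- function(frames, unique_contigs, min_anchor = 300,
                           min_identity = 0.6, read_seq = NULL) {
  f <- frames |>
    filter(.data$contig %in% unique_contigs,
           .data$anchor_span >= min_anchor,
           .data$identity >= min_identity) |>
    dedupe_frames()
  if (nrow(f) < 2) return(empty_placements())

  out <- map(seq_len(nrow(f) - 1), function(i) {
    a <- f[i, ]; b <- f[i + 1, ]
    gap <- b$frame_start - a$frame_end
    p1 <- port(a$contig, if (a$orientation == "+") "tail" else "head")
    p2 <- port(b$contig, if (b$orientation == "+") "head" else "tail")
    if (p1 == p2) return(NULL)
    gap_seq <- NA_character_
    if (!is.null(read_seq) && gap >= 0 &&
        a$frame_end >= 0 && b$frame_start <= a$read_length) {
      gap_seq <- if (gap == 0) "" else
        substr(read_seq, a$frame_end + 1, b$frame_start)
    }
    if (p1 > p2) {  # canonical order; fill sequence follows end1 -> end2
      tmp <- p1; p1 <- p2; p2 <- tmp
      if (!is.na(gap_seq) && nzchar(gap_seq)) gap_seq <- revcomp(gap_seq)
    }
    tibble(end1 = p1, end2 = p2, gap = gap,
           quality = min(a$identity, b$identity),
           read_name = a$read_name, gap_seq = gap_seq)
  })
  res <- bind_rows(out)
  if (nrow(res) == 0) empty_placements() else res
}

empty_placements <- function() {
  tibble(end1 = character(), end2 = character(), gap = numeric(),
         quality = numeric(), read_name = character(),
         gap_seq = character())
}
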