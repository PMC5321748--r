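#' Create an empty bridge set
#'
#' A bridge aggregates all read placements that consistently support one
#' relative position (distance + orientation) of a pair of unique-contig
#' ends. Bridges live in a tibble with one row per bridge and a list-column
#' of supporting placements.
#'
#' @return an empty bridge tibble.
#' @export
new_bridge_set <- function() {
  tibble(
    bridge_id = integer(), end1 = character(), end2 = character(),
    consensus_gap = numeric(), score = numeric(), n_supports = integer(),
    committed = logical(), supports = list(), fill = list()
  )
}

#' Bridge score
#'
#' Sum over supports of the per-read anchor quality q in (0, 1] (identity of
#' the weaker of the two anchors); strictly increasing in support count.
#'
#' @param supports a support tibble (`read_name`, `gap`, `quality`,
#'   `gap_seq`).
#' @return non-negative numeric score.
#' @export
score_bridge <- function(supports) {
  if (is.null(supports) || nrow(supports) == 0) return(0)
  sum(supports$quality)
}

gap_tolerance <- function(gap, gap_tol_bp = 200, gap_tol_frac = 0.2) {
  pmax(gap_tol_bp, gap_tol_frac * abs(gap))
}

#' Accrete placements into bridges
#'
#' Each placement joins the existing bridge on the same canonical endpoint
#' pair whose consensus gap it matches within tolerance
#' (`max(gap_tol_bp, gap_tol_frac * |consensus|)`); otherwise it founds a
#' new bridge on that pair — a second bridge on the same endpoints is a
#' contradiction candidate resolved at commit time. The consensus gap is the
#' quality-weighted median of supporting gaps (robust to single chimeric
#' reads) and the score is updated per [score_bridge()].
#'
#' @param bridges bridge tibble ([new_bridge_set()]).
#' @param placements placement tibble from [spanning_pairs()].
#' @param gap_tol_bp absolute gap tolerance floor in bases (default 200).
#' @param gap_tol_frac relative gap tolerance (default 0.2).
#' @return updated bridge tibble.
#' @export
accrete <- function(bridges, placements, gap_tol_bp = 200,
                    gap_tol_frac = 0.2) {
  for (i in seq_len(nrow(placements))) {
    p <- placements[i, ]
    cand <- which(bridges$end1 == p$end1 & bridges$end2 == p$end2)
    hit <- NA_integer_
    if (length(cand) > 0) {
      dev <- abs(bridges$consensus_gap[cand] - p$gap)
      ok <- dev <= gap_tolerance(bridges$consensus_gap[cand],
                                 gap_tol_bp, gap_tol_frac)
      if (any(ok)) hit <- cand[ok][which.min(dev[ok])]
    }
    sup <- tibble(read_name = p$read_name, gap = p$gap,
                  quality = p$quality, gap_seq = p$gap_seq)
    if (is.na(hit)) {
      bridges <- add_row(
        bridges,
        bridge_id = if (nrow(bridges) == 0) 1L else max(bridges$bridge_id) + 1L,
        end1 = p$end1, end2 = p$end2,
        consensus_gap = p$gap, score = p$quality, n_supports = 1L,
        committed = FALSE, supports = list(sup), fill = list(NULL)
      )
    } else {
      sups <- bind_rows(bridges$supports[[hit]], sup)
      bridges$supports[[hit]] <- sups
      bridges$consensus_gap[hit] <- weighted_median(sups$gap, sups$quality)
      bridges$score[hit] <- score_bridge(sups)
      bridges$n_supports[hit] <- nrow(sups)
    }
  }
  bridges
}
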