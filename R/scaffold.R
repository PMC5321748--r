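#' Create a scaffold state over classified contigs
#'
#' The scaffold state is the growing layout of the assembly: each unique
#' contig exposes two "ports" (head, tail) and every committed bridge
#' occupies one port on each of its two endpoints. Because a port carries at
#' most one committed bridge, the committed set always decomposes into
#' simple paths (linear scaffolds) and cycles (circular replicons) — no
#' extra bookkeeping is needed to keep layouts consistent.
#'
#' @param contigs contig tibble with `multiplicity`/`is_unique` set
#'   ([classify_contigs()]).
#' @return an object of class `scaffold_state`.
#' @export
new_scaffold_state <- function(contigs) {
  if (anyNA(contigs$is_unique)) {
    abort("contigs must be classified before scaffolding (see classify_contigs)")
  }
  structure(
    list(
      contigs = contigs,
      bridges = tibble(
        bridge_id = integer(), end1 = character(), end2 = character(),
        gap = numeric(), score = numeric(),
        supports = list(), fill = list()
      )
    ),
    class = "scaffold_state"
  )
}

#' @export
print.scaffold_state <- function(x, ...) {
  lay <- scaffold_layout(x)
  cat(sprintf(
    "<scaffold_state> %d unique contig(s) in %d scaffold(s), %d circular; %d committed bridge(s)\n",
    sum(x$contigs$is_unique), length(unique(lay$scaffold)),
    length(unique(lay$scaffold[lay$circular])), nrow(x$bridges)))
  invisible(x)
}

state_port_owner <- function(state) {
  br <- state$bridges
  stats::setNames(rep(br$bridge_id, 2L), c(br$end1, br$end2))
}

#' Commit a bridge into the scaffold layout
#'
#' Joins the two contig ends named by the bridge. Both ports must be free;
#' joining the two free ends of one path closes it into a circular
#' component (this is how plasmids and chromosomes circularize, including a
#' single contig bridged tail-to-head by reads wrapping the origin). A
#' bridge landing on an occupied port signals a condition of class
#' `longscaff_conflict` carrying the ids of the committed bridges in the
#' way; see [resolve_conflict()].
#'
#' @param state a `scaffold_state`.
#' @param bridge one bridge row (from the bridge tibble) with at least
#'   `bridge_id`, `end1`, `end2`, `consensus_gap` (or `gap`), `score`,
#'   and optionally `supports`.
#' @return the updated state.
#' @export
merge_contigs <- function(state, bridge) {
  gap <- bridge$consensus_gap %||% bridge$gap
  if (is.null(gap)) abort("bridge has no gap estimate")
  uniq <- state$contigs$name[state$contigs$is_unique]
  ends <- c(bridge$end1, bridge$end2)
  bad <- setdiff(port_contig(ends), uniq)
  if (length(bad) > 0) {
    abort(paste0("bridge endpoints must be unique contigs; offending: ",
                 paste(bad, collapse = ", ")))
  }
  owner <- state_port_owner(state)
  occ <- stats::na.omit(owner[ends])
  if (length(occ) > 0) {
    abort(
      sprintf("endpoint(s) already occupied by committed bridge(s) %s",
              paste(unique(occ), collapse = ",")),
      class = "longscaff_conflict",
      conflicts = unique(unname(occ))
    )
  }
  sups <- if (!is.null(bridge$supports)) bridge$supports[[1]] else NULL
  state$bridges <- add_row(
    state$bridges,
    bridge_id = bridge$bridge_id, end1 = bridge$end1, end2 = bridge$end2,
    gap = gap, score = bridge$score,
    supports = list(sups), fill = list(NULL)
  )
  state
}

uncommit_bridge <- function(state, bid) {
  state$bridges <- filter(state$bridges, .data$bridge_id != bid)
  state
}

#' Resolve a conflicting bridge against the committed layout
#'
#' Implements the streaming repair rule: when a new bridge contradicts the
#' existing layout, the smallest-scoring contradicting committed bridge is
#' broken (its join undone — component splits and offsets recompute on the
#' next layout pass) provided the new bridge outscores it; otherwise the new
#' bridge stays pending and may win later as it gains supports. When several
#' committed bridges conflict simultaneously, minima are broken one at a
#' time while the new bridge still outscores the current minimum.
#'
#' @param state a `scaffold_state`.
#' @param bridge the incoming bridge row.
#' @return list with `state`, `committed` (logical), and `broken`
#'   (integer vector of bridge ids removed).
#' @export
resolve_conflict <- function(state, bridge) {
  broken <- integer()
  repeat {
    res <- tryCatch(
      list(state = merge_contigs(state, bridge), committed = TRUE),
      longscaff_conflict = function(e) e
    )
    if (is.list(res) && isTRUE(res$committed)) {
      return(list(state = res$state, committed = TRUE, broken = broken))
    }
    conflicts <- res$conflicts
    sc <- state$bridges$score[match(conflicts, state$bridges$bridge_id)]
    if (bridge$score <= min(sc)) {
      return(list(state = state, committed = FALSE, broken = broken))
    }
    loser <- conflicts[which.min(sc)]
    state <- uncommit_bridge(state, loser)
    broken <- c(broken, loser)
  }
}

# Walk the port graph from an entry port; a cycle is detected when the walk
# returns to the entry port itself.
walk_component <- function(entry, port_map, lens) {
  contigs <- character(); oris <- character()
  gaps_in <- numeric(); bids_in <- integer()
  cur <- entry
  repeat {
    cname <- port_contig(cur)
    contigs <- c(contigs, cname)
    oris <- c(oris, if (port_end(cur) == "head") "+" else "-")
    exit <- other_port(cur)
    link <- port_map[[exit]]
    if (is.null(link)) {
      return(list(contigs = contigs, oris = oris, gaps_in = gaps_in,
                  bids_in = bids_in, circular = FALSE, exit = exit,
                  closing_gap = NA_real_, closing_bid = NA_integer_))
    }
    if (link$to == entry) {
      return(list(contigs = contigs, oris = oris, gaps_in = gaps_in,
                  bids_in = bids_in, circular = TRUE, exit = exit,
                  closing_gap = link$gap, closing_bid = link$bid))
    }
    gaps_in <- c(gaps_in, link$gap)
    bids_in <- c(bids_in, link$bid)
    cur <- link$to
  }
}

#' Lay out the scaffold state as a segment table
#'
#' Traverses each component deterministically (linear components oriented so
#' the first contig name sorts before the last; circular components started
#' at their lexicographically smallest contig in `+` orientation) and
#' assigns 0-based half-open scaffold offsets: each segment starts at the
#' previous segment's end plus the connecting bridge's gap (negative gaps
#' overlap and are trimmed at materialization). Scaffolds are numbered by
#' decreasing laid-out span.
#'
#' @param state a `scaffold_state`.
#' @return layout tibble: `scaffold`, `scaffold_name`, `part`, `contig`,
#'   `orientation`, `start`, `end`, `gap_before`, `bridge_in`, `circular`,
#'   `closing_gap`, `closing_bridge`.
#' @export
scaffold_layout <- function(state) {
  u <- filter(state$contigs, .data$is_unique)
  lens <- stats::setNames(u$length, u$name)
  br <- state$bridges
  port_map <- list()
  for (i in seq_len(nrow(br))) {
    port_map[[br$end1[i]]] <- list(bid = br$bridge_id[i], to = br$end2[i],
                                   gap = br$gap[i])
    port_map[[br$end2[i]]] <- list(bid = br$bridge_id[i], to = br$end1[i],
                                   gap = br$gap[i])
  }

  comps <- list()
  done <- character()
  for (cname in sort(u$name)) {
    if (cname %in% done) next
    w <- walk_component(port(cname, "head"), port_map, lens)
    if (w$circular) {
      m <- min(w$contigs)
      w <- walk_component(port(m, "head"), port_map, lens)
    } else {
      w <- walk_component(w$exit, port_map, lens)  # from one true terminal
      n <- length(w$contigs)
      if (w$contigs[1] > w$contigs[n] || (n == 1 && w$oris[1] == "-")) {
        w <- walk_component(w$exit, port_map, lens)  # canonical direction
      }
    }
    done <- c(done, w$contigs)
    comps[[length(comps) + 1L]] <- w
  }

  rows <- imap(comps, function(w, ci) {
    n <- length(w$contigs)
    starts <- numeric(n); ends <- numeric(n)
    starts[1] <- 0; ends[1] <- lens[[w$contigs[1]]]
    if (n > 1) {
      for (k in 2:n) {
        starts[k] <- ends[k - 1] + w$gaps_in[k - 1]
        ends[k] <- starts[k] + lens[[w$contigs[k]]]
      }
    }
    if (n > 1 && any(diff(starts) <= 0)) {
      abort(sprintf("layout integrity: non-increasing offsets in component containing %s",
                    w$contigs[1]))
    }
    tibble(
      component = ci, part = seq_len(n), contig = w$contigs,
      orientation = w$oris, start = starts, end = ends,
      gap_before = c(NA_real_, w$gaps_in),
      bridge_in = c(NA_integer_, w$bids_in),
      circular = w$circular,
      closing_gap = w$closing_gap, closing_bridge = w$closing_bid
    )
  })
  lay <- bind_rows(rows)
  if (nrow(lay) == 0) {
    return(tibble(
      scaffold = integer(), scaffold_name = character(), part = integer(),
      contig = character(), orientation = character(), start = numeric(),
      end = numeric(), gap_before = numeric(), bridge_in = integer(),
      circular = logical(), closing_gap = numeric(),
      closing_bridge = integer()))
  }

  spans <- lay |>
    group_by(.data$component) |>
    summarise(
      span = max(.data$end) +
        ifelse(.data$circular[1] & !is.na(.data$closing_gap[1]) &
                 .data$closing_gap[1] > 0, .data$closing_gap[1], 0),
      first_contig = .data$contig[1], .groups = "drop"
    ) |>
    arrange(desc(.data$span), .data$first_contig) |>
    mutate(scaffold = row_number())

  lay |>
    left_join(select(spans, "component", "scaffold"), by = "component") |>
    mutate(scaffold_name = paste0("scaffold_", .data$scaffold,
                                  ifelse(.data$circular, "_circular", ""))) |>
    arrange(.data$scaffold, .data$part) |>
    select("scaffold", "scaffold_name", "part", "contig", "orientation",
           "start", "end", "gap_before", "bridge_in", "circular",
           "closing_gap", "closing_bridge")
}

#' Validate scaffold-state invariants
#'
#' Checks that every port carries at most one committed bridge, every
#' unique contig appears exactly once in the layout, offsets strictly
#' increase within each scaffold, and circular components have a committed
#' closing bridge. Used after every mutation in the test-suite.
#'
#' @param state a `scaffold_state`.
#' @return `TRUE` invisibly; aborts on violation.
#' @export
validate_scaffold_state <- function(state) {
  br <- state$bridges
  ports <- c(br$end1, br$end2)
  if (anyDuplicated(ports) > 0) abort("invariant: port used by >1 committed bridge")
  lay <- scaffold_layout(state)
  u <- state$contigs$name[state$contigs$is_unique]
  if (!identical(sort(lay$contig), sort(u))) {
    abort("invariant: unique contigs not in one-to-one layout correspondence")
  }
  circ <- filter(lay, .data$circular)
  if (nrow(circ) > 0 && anyNA(circ$closing_bridge)) {
    abort("invariant: circular component without closing bridge")
  }
  invisible(TRUE)
}

#' Scaffold all bridges at once (batch mode)
#'
#' Greedy Kruskal-style pass over the finalized bridge set: bridges are
#' sorted by decreasing score (ties by endpoint names), filtered by the
#' commit threshold, and committed in order, skipping any whose ports are
#' already taken — no repair pass is needed because higher-scoring bridges
#' always land first. Gap fills are computed for each committed bridge.
#'
#' @param contigs classified contig tibble.
#' @param bridges bridge tibble ([accrete()]).
#' @param min_score commit threshold on the bridge score (default 1.0: one
#'   high-identity spanning read suffices).
#' @param min_support minimum number of supporting reads (default 1).
#' @param min_fill_identity see [fill_gap()].
#' @return a `scaffold_state`.
#' @export
batch_scaffold <- function(contigs, bridges, min_score = 1,
                           min_support = 1L, min_fill_identity = 0.75) {
  state <- new_scaffold_state(contigs)
  elig <- bridges |>
    filter(.data$score >= min_score, .data$n_supports >= min_support) |>
    arrange(desc(.data$score), .data$end1, .data$end2)
  for (i in seq_len(nrow(elig))) {
    state <- tryCatch(
      merge_contigs(state, elig[i, ]),
      longscaff_conflict = function(e) state
    )
  }
  compute_fills(state, min_fill_identity = min_fill_identity)
}

#' @export
tidy.scaffold_state <- function(x, ...) scaffold_layout(x)

#' @export
glance.scaffold_state <- function(x, ...) {
  asm <- materialize_assembly(x)
  st <- compute_stats(nchar(asm$sequences))
  tibble(n_sequences = st$n_sequences, n50 = st$n50,
         n_circular = sum(asm$circular),
         committed_bridges = nrow(x$bridges))
}
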