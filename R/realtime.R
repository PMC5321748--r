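default_config <- function(...) {
  cfg <- list(
    min_anchor = 300, min_identity = 0.6,
    gap_tol_bp = 200, gap_tol_frac = 0.2,
    min_score = 1, min_support = 1L, min_fill_identity = 0.75,
    report_every = 100L,
    target_n_sequences = NULL, stop_all_circular = FALSE,
    stall_batches = 50L
  )
  upd <- list(...)
  unknown <- setdiff(names(upd), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown config option(s): ", paste(unknown, collapse = ", ")))
  }
  cfg[names(upd)] <- upd
  cfg
}

# component membership: contig -> scaffold_name, from the current layout
component_of <- function(state) {
  lay <- scaffold_layout(state)
  stats::setNames(lay$scaffold_name, lay$contig)
}

state_report <- function(state, batch, bases, reads) {
  asm <- materialize_assembly(state)
  lens <- nchar(asm$sequences)
  keep <- lens >= 500
  st <- if (any(keep)) compute_stats(lens) else
    tibble(n_sequences = 0L, n50 = NA_real_)
  tibble(
    timestamp = batch, bases_received = bases, reads_received = reads,
    n_sequences = st$n_sequences, n50 = st$n50,
    n_circular = sum(asm$circular[keep])
  )
}

#' Decide whether a streaming run may stop
#'
#' Pure function of the report timeline: stop when the target number of
#' output sequences is reached, when every reported sequence is circular
#' (`stop_all_circular`), or when no report field has changed for
#' `stall_batches` consecutive batches.
#'
#' @param timeline report tibble (rows in batch order).
#' @param config list from `default_config()` entries
#'   `target_n_sequences`, `stop_all_circular`, `stall_batches`.
#' @return `"stop"` or `"continue"`.
#' @export
stop_condition <- function(timeline, config = list()) {
  cfg <- do.call(default_config, config)
  if (nrow(timeline) == 0) return("continue")
  cur <- timeline[nrow(timeline), ]
  if (!is.null(cfg$target_n_sequences) &&
      cur$n_sequences <= cfg$target_n_sequences) return("stop")
  if (isTRUE(cfg$stop_all_circular) && cur$n_sequences > 0 &&
      cur$n_circular == cur$n_sequences) return("stop")
  n <- cfg$stall_batches
  if (nrow(timeline) > n) {
    recent <- timeline[(nrow(timeline) - n):nrow(timeline),
                       c("n_sequences", "n50", "n_circular")]
    if (nrow(distinct(recent)) == 1) return("stop")
  }
  "continue"
}

# one commit sweep: greedily commit eligible bridges (highest score first)
# with conflict repair, until nothing more commits
commit_sweep <- function(state, bridges, cfg, batch, decisions) {
  repeat {
    elig <- bridges |>
      filter(!.data$committed, .data$score >= cfg$min_score,
             .data$n_supports >= cfg$min_support) |>
      arrange(desc(.data$score), .data$end1, .data$end2)
    if (nrow(elig) == 0) break
    progressed <- FALSE
    for (i in seq_len(nrow(elig))) {
      b <- elig[i, ]
      comp_before <- component_of(state)
      res <- resolve_conflict(state, b)
      if (length(res$broken) > 0) {
        rows <- match(res$broken, bridges$bridge_id)
        bridges$committed[rows] <- FALSE
        decisions <- bind_rows(decisions, tibble(
          batch = batch, event = "break", bridge_id = res$broken,
          end1 = bridges$end1[rows], end2 = bridges$end2[rows],
          score = bridges$score[rows]))
      }
      if (res$committed) {
        state <- res$state
        bridges$committed[match(b$bridge_id, bridges$bridge_id)] <- TRUE
        same_comp <- !is.na(comp_before[port_contig(b$end1)]) &&
          identical(comp_before[[port_contig(b$end1)]],
                    comp_before[[port_contig(b$end2)]])
        decisions <- bind_rows(decisions, tibble(
          batch = batch, event = if (same_comp) "circularize" else "commit",
          bridge_id = b$bridge_id, end1 = b$end1, end2 = b$end2,
          score = b$score))
        state <- compute_fills(state, cfg$min_fill_identity,
                               only = b$bridge_id)
        progressed <- TRUE
        break  # re-rank eligibility after every layout change
      } else {
        decisions <- bind_rows(decisions, tibble(
          batch = batch, event = "conflict", bridge_id = b$bridge_id,
          end1 = b$end1, end2 = b$end2, score = b$score))
      }
    }
    if (!progressed) break
  }
  list(state = state, bridges = bridges, decisions = decisions)
}

# keep committed-bridge copies in sync with the evolving bridge set
sync_committed <- function(state, bridges, cfg) {
  for (i in seq_len(nrow(state$bridges))) {
    j <- match(state$bridges$bridge_id[i], bridges$bridge_id)
    if (is.na(j)) next
    changed <- bridges$n_supports[j] !=
      nrow(state$bridges$supports[[i]] %||% tibble())
    if (!changed) next
    gap_moved <- abs(bridges$consensus_gap[j] - state$bridges$gap[i]) >
      0.1 * max(1, abs(state$bridges$gap[i]))
    old_best <- max(c(0, state$bridges$supports[[i]]$quality))
    new_best <- max(c(0, bridges$supports[[j]]$quality))
    state$bridges$gap[i] <- bridges$consensus_gap[j]
    state$bridges$score[i] <- bridges$score[j]
    state$bridges$supports[[i]] <- bridges$supports[[j]]
    # a settled repeat fill is short-read-accurate; a better backbone read
    # cannot improve it
    settled <- !is.null(state$bridges$fill[[i]]) &&
      identical(state$bridges$fill[[i]]$source, "repeat_contig")
    if ((gap_moved || new_best > old_best + 0.01) && !settled) {
      state <- compute_fills(state, cfg$min_fill_identity,
                             only = state$bridges$bridge_id[i])
    }
  }
  state
}

#' Run the streaming scaffolder over an alignment stream
#'
#' Processes long-read-to-contig alignments in generation order: per read,
#' contig frames are projected and spanning placements accreted into
#' bridges; after every batch of `report_every` reads, bridges that reached
#' the commit threshold are merged into the scaffold (greedy by score, with
#' conflict repair), gap fills refreshed, and an assembly report appended.
#' "Real time" is modeled purely as stream order — no wall clock — so runs
#' are deterministic.
#'
#' @param contigs classified contig tibble ([classify_contigs()]).
#' @param alignments alignment tibble, or a path to a PAF/SAM file.
#' @param format `"paf"` or `"sam"` when `alignments` is a path.
#' @param reads optional read sequences for gap filling: a named character
#'   vector or a FASTQ/FASTA path. Without them positive gaps are N-filled.
#' @param features optional BED-style feature tibble
#'   (`contig`, `start`, `end`, `name`, `strand`) tracked live.
#' @param plasmid_flags character vector of contig names carrying a plasmid
#'   origin of replication.
#' @param ... configuration overrides: `min_anchor`, `min_identity`,
#'   `gap_tol_bp`, `gap_tol_frac`, `min_score`, `min_support`,
#'   `min_fill_identity`, `report_every`, `target_n_sequences`,
#'   `stop_all_circular`, `stall_batches`.
#' @return list with `state`, `assembly`, `timeline`, `decisions`,
#'   `bridges`, `features` (final placements), `feature_events`
#'   (replicon-status changes with the cumulative bases at which they
#'   happened), and `stopped_early`.
#' @export
run_streaming <- function(contigs, alignments, format = c("paf", "sam"),
                          reads = NULL, features = NULL,
                          plasmid_flags = character(), ...) {
  cfg <- default_config(...)
  format <- match.arg(format)
  if (is.character(alignments) && length(alignments) == 1) {
    alignments <- if (format == "paf") read_paf(alignments)
                  else read_sam(alignments)
  }
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", reads)) "fastq" else "fasta"
    rs <- Biostrings::readDNAStringSet(reads, format = fmt)
    reads <- stats::setNames(as.character(rs), sub("\\s.*$", "", names(rs)))
  }

  alignments$contig <- normalize_contig_names(alignments$contig)
  known <- contigs$name
  bad <- setdiff(unique(alignments$contig), known)
  if (length(bad) > 0) {
    abort(paste0("alignment references unknown contig(s): ",
                 paste(bad, collapse = ", ")))
  }
  uniq <- contigs$name[contigs$is_unique]

  state <- new_scaffold_state(contigs)
  bridges <- new_bridge_set()
  decisions <- tibble(batch = integer(), event = character(),
                      bridge_id = integer(), end1 = character(),
                      end2 = character(), score = numeric())
  timeline <- list()
  groups <- alignment_batches(alignments)
  bases <- 0; nreads <- 0; batch <- 0L; stopped <- FALSE

  idx <- seq_along(groups)
  chunks <- if (length(idx) > 0) split(idx, ceiling(idx / cfg$report_every))
            else list()
  feat_status <- NULL
  feature_events <- tibble(name = character(), status = character(),
                           batch = integer(), bases_received = numeric())

  for (chunk in chunks) {
    batch <- batch + 1L
    for (g in chunk) {
      grp <- groups[[g]]
      nreads <- nreads + 1
      bases <- bases + grp$read_length[1]
      frames <- compute_frames(grp)
      rseq <- if (!is.null(reads)) reads[[grp$read_name[1]]] else NULL
      pl <- spanning_pairs(frames, uniq, min_anchor = cfg$min_anchor,
                           min_identity = cfg$min_identity,
                           read_seq = rseq)
      bridges <- accrete(bridges, pl, gap_tol_bp = cfg$gap_tol_bp,
                         gap_tol_frac = cfg$gap_tol_frac)
    }
    state <- sync_committed(state, bridges, cfg)
    sw <- commit_sweep(state, bridges, cfg, batch, decisions)
    state <- sw$state; bridges <- sw$bridges; decisions <- sw$decisions

    timeline[[batch]] <- state_report(state, batch, bases, nreads)
    tl <- bind_rows(timeline)

    if (!is.null(features)) {
      pf <- place_features(features, state, plasmid_flags)
      changed <- if (is.null(feat_status)) pf else
        anti_join(pf[, c("name", "replicon_status")],
                  feat_status[, c("name", "replicon_status")],
                  by = c("name", "replicon_status"))
      if (nrow(changed) > 0) {
        feature_events <- bind_rows(feature_events, tibble(
          name = changed$name, status = changed$replicon_status,
          batch = batch, bases_received = bases))
      }
      feat_status <- pf
    }

    if (stop_condition(tl, cfg) == "stop") { stopped <- TRUE; break }
  }

  # final fill refresh over the complete support sets, so the streamed
  # layout is byte-identical to a batch pass over the same bridges; the
  # closing report is recomputed against it
  if (nrow(state$bridges) > 0) {
    state <- compute_fills(state, cfg$min_fill_identity,
                           only = state$bridges$bridge_id)
  }
  if (batch > 0) {
    timeline[[batch]] <- state_report(state, batch, bases, nreads)
  }

  timeline <- if (length(timeline) > 0) bind_rows(timeline) else tibble(
    timestamp = integer(), bases_received = numeric(),
    reads_received = numeric(), n_sequences = integer(), n50 = integer(),
    n_circular = integer())
  final_features <- if (!is.null(features))
    place_features(features, state, plasmid_flags) else NULL
  list(
    state = state, assembly = materialize_assembly(state),
    timeline = timeline, decisions = decisions, bridges = bridges,
    features = final_features, feature_events = feature_events,
    stopped_early = stopped
  )
}

#' Lift contig features through the scaffold layout
#'
#' Features annotated on contigs (0-based half-open BED convention) are
#' translated to scaffold coordinates through their contig's placement
#' (offset plus orientation; minus-strand placements flip the interval and
#' the feature strand). A feature's replicon status reflects its component:
#' `plasmid` when any contig of the component is flagged as carrying a
#' plasmid origin, upgraded to `circular_plasmid` when that component is
#' circular; a circular unflagged component is called `chromosome`;
#' everything else is `unassigned`. Features on repetitive contigs keep
#' their contig coordinates (a multi-copy element has no single scaffold
#' position).
#'
#' @param features tibble with `contig`, `start`, `end`, and optionally
#'   `name`, `strand`.
#' @param state a `scaffold_state`.
#' @param plasmid_flags character vector of flagged contig names.
#' @return tibble: input columns plus `scaffold_name`, `scaffold_start`,
#'   `scaffold_end`, `scaffold_strand`, `replicon_status`.
#' @export
place_features <- function(features, state, plasmid_flags = character()) {
  features <- as_tibble(features)
  if (!"name" %in% names(features)) {
    features$name <- paste0("feature_", seq_len(nrow(features)))
  }
  if (!"strand" %in% names(features)) features$strand <- "+"
  known <- state$contigs$name
  bad <- !(features$contig %in% known)
  if (any(bad)) {
    warn(paste0("skipping feature(s) on unknown contig(s): ",
                paste(unique(features$contig[bad]), collapse = ", ")))
    features <- features[!bad, ]
  }
  lay <- scaffold_layout(state)
  flagged_comp <- unique(lay$scaffold_name[lay$contig %in% plasmid_flags])
  circ_comp <- unique(lay$scaffold_name[lay$circular])
  clen <- stats::setNames(state$contigs$length, state$contigs$name)

  rows <- map(seq_len(nrow(features)), function(i) {
    f <- features[i, ]
    seg <- lay[lay$contig == f$contig, ]
    if (nrow(seg) == 0) {  # repetitive or unplaced contig
      status <- if (f$contig %in% plasmid_flags) "plasmid" else "unassigned"
      return(mutate(f, scaffold_name = f$contig, scaffold_start = f$start,
                    scaffold_end = f$end, scaffold_strand = f$strand,
                    replicon_status = status))
    }
    L <- clen[[f$contig]]
    if (seg$orientation == "+") {
      s <- seg$start + f$start
    } else {
      s <- seg$start + (L - f$end)
    }
    lifted_strand <- if (seg$orientation == "-") {
      if (f$strand == "+") "-" else "+"
    } else f$strand
    comp <- seg$scaffold_name
    status <- if (comp %in% flagged_comp) {
      if (comp %in% circ_comp) "circular_plasmid" else "plasmid"
    } else if (comp %in% circ_comp) "chromosome" else "unassigned"
    mutate(f, scaffold_name = comp, scaffold_start = s,
           scaffold_end = s + (f$end - f$start),
           scaffold_strand = lifted_strand,
           replicon_status = status)
  })
  bind_rows(rows)
}

#' Plot a streaming report timeline
#'
#' Draws N50, output sequence count, and circular-sequence count against
#' cumulative long-read bases — the live view used to decide when enough
#' data has been sequenced.
#'
#' @param object report timeline tibble (`timeline` from
#'   [run_streaming()]).
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.longscaff_timeline <- function(object, ...) {
  long <- object |>
    select("bases_received", "n_sequences", "n50", "n_circular") |>
    tidyr::pivot_longer(-"bases_received",
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$bases_received, .data$value)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "cumulative long-read bases", y = NULL,
                  title = "Assembly progress during streaming scaffolding")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Timeline plot helper
#'
#' Tags a timeline tibble so [ggplot2::autoplot()] dispatches to the
#' streaming-progress plot.
#'
#' @param timeline report tibble from [run_streaming()].
#' @return the tibble with class `longscaff_timeline` prepended.
#' @export
as_timeline <- function(timeline) {
  class(timeline) <- c("longscaff_timeline", class(timeline))
  timeline
}
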