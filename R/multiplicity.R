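#' Estimate whole-genome sequencing depth from the largest contigs
#'
#' The genome-wide short-read depth is estimated as the length-weighted mean
#' depth of a prefix of the largest contigs, on the premise that the largest
#' contigs of a bacterial assembly are almost always single-copy. Starting
#' from the largest contig, contigs are accepted one by one while their depth
#' stays within a factor `theta` of the running estimate; accumulation also
#' stops after `max_contigs` contigs or at the first contig shorter than
#' `min_contig_len`.
#'
#' @param contigs contig tibble from [read_contigs()], sorted by decreasing
#'   length (as that function returns it).
#' @param theta depth-ratio threshold separating single-copy from repeat
#'   coverage (default 1.5, unitless, must be > 1).
#' @param max_contigs maximum number of contigs entering the estimate
#'   (default 20).
#' @param min_contig_len contigs shorter than this never enter the estimate
#'   (default 20000 bases).
#' @param depth_stop `"symmetric"` (default) stops when the next contig's
#'   depth ratio to the estimate exceeds `theta` in either direction, so
#'   abnormally low-coverage large contigs also terminate accumulation;
#'   `"high-only"` stops only on high ratios.
#' @return an object of class `depth_model` with fields `genome_depth`,
#'   `theta`, `contigs_used`, `max_contigs`, `min_contig_len`, and the names
#'   of the contigs used.
#' @export
estimate_genome_depth <- function(contigs, theta = 1.5, max_contigs = 20,
                                  min_contig_len = 20000,
                                  depth_stop = c("symmetric", "high-only")) {
  depth_stop <- match.arg(depth_stop)
  stopifnot(theta > 1, max_contigs >= 1)
  if (nrow(contigs) == 0) abort("no contigs: cannot estimate genome depth")
  contigs <- arrange(contigs, desc(.data$length), .data$name)

  depth_g <- contigs$depth[1]
  wsum <- contigs$depth[1] * contigs$length[1]
  lsum <- contigs$length[1]
  used <- 1L
  while (used < min(max_contigs, nrow(contigs))) {
    nxt <- used + 1L
    if (contigs$length[nxt] < min_contig_len) break
    ratio <- contigs$depth[nxt] / depth_g
    hi <- ratio > theta
    lo <- (1 / ratio) > theta
    if (hi || (depth_stop == "symmetric" && lo)) break
    wsum <- wsum + contigs$depth[nxt] * contigs$length[nxt]
    lsum <- lsum + contigs$length[nxt]
    depth_g <- wsum / lsum
    used <- nxt
  }

  structure(
    list(genome_depth = depth_g, theta = theta, contigs_used = used,
         max_contigs = max_contigs, min_contig_len = min_contig_len,
         depth_stop = depth_stop, contig_names = contigs$name[seq_len(used)]),
    class = "depth_model"
  )
}

#' Classify contigs as unique or repetitive by copy number
#'
#' The multiplicity (estimated genomic copy number) of a contig is its depth
#' ratio to the genome depth, rounded half-up and floored at 1. A contig is
#' unique when the raw (unrounded) ratio is below the model's `theta`, so a
#' ratio of 1.49 is unique at the default threshold while 1.51 is repetitive.
#'
#' @param contigs contig tibble.
#' @param model a `depth_model` from [estimate_genome_depth()].
#' @return the contig tibble with `multiplicity` and `is_unique` filled in.
#' @export
classify_contigs <- function(contigs, model) {
  stopifnot(inherits(model, "depth_model"))
  contigs |>
    mutate(
      ratio = .data$depth / model$genome_depth,
      is_unique = .data$ratio < model$theta,
      multiplicity = as.integer(pmax(1, round_half_up(.data$ratio)))
    ) |>
    select(-"ratio")
}

#' @export
print.depth_model <- function(x, ...) {
  cat(sprintf(
    "<depth_model> genome depth %.2fx from %d contig(s) (theta=%g, %s stop)\n",
    x$genome_depth, x$contigs_used, x$theta, x$depth_stop))
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' @export
glance.depth_model <- function(x, ...) {
  tibble(genome_depth = x$genome_depth, theta = x$theta,
         contigs_used = x$contigs_used, depth_stop = x$depth_stop)
}

#' @export
tidy.depth_model <- function(x, ...) {
  tibble(contig = x$contig_names, rank = seq_along(x$contig_names))
}
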