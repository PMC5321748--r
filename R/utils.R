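#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map2 map_dbl map_chr map_int pmap keep imap
NULL

# Weighted median: smallest x with cumulative weight >= half the total.
weighted_median <- function(x, w = rep(1, length(x))) {
  stopifnot(length(x) == length(w), all(w >= 0))
  if (length(x) == 0L) return(NA_real_)
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  x[which(cw >= sum(w) / 2)[1L]]
}

# Round-half-up (base round() is round-half-even).
round_half_up <- function(x) floor(x + 0.5)

#' Reverse-complement a DNA string
#'
#' `N` maps to `N`; input is assumed upper-case A/C/G/T/N.
#'
#' @param x character scalar (or vector) of DNA.
#' @return character of the same length, reverse-complemented.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Contig-end "ports": a scaffold join attaches to the head or tail of a
# contig; a port is free until a committed bridge occupies it.
port <- function(contig, end) paste0(contig, ":", end)
port_contig <- function(p) sub(":[^:]+$", "", p)
port_end <- function(p) sub("^.*:", "", p)
other_end <- function(end) ifelse(end == "head", "tail", "head")
other_port <- function(p) port(port_contig(p), other_end(port_end(p)))

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
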