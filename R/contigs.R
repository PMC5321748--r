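#' Read short-read assembly contigs with per-contig depth
#'
#' Reads a contig FASTA and attaches a sequencing depth to every contig.
#' Depth is taken from SPAdes-style headers (`NODE_<i>_length_<L>_cov_<c>`)
#' when present; a two-column tab-delimited coverage table
#' (`contig_name<TAB>depth`, no header) overrides header values and covers
#' assemblers that do not embed depth. Sequences are upper-cased on ingestion
#' and the result is sorted by decreasing length (ties broken by name) as
#' required downstream by genome-depth estimation.
#'
#' @param fasta path to the contig FASTA file.
#' @param coverage_table optional path to a 2-column TSV of `name`, `depth`.
#' @return a tibble with one row per contig: `id`, `name`, `sequence`,
#'   `length`, `depth`, and placeholder columns `multiplicity`, `is_unique`
#'   (NA until [classify_contigs()]).
#' @export
read_contigs <- function(fasta, coverage_table = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  parse_contig_depths(
    tibble(
      name = sub("\\s.*$", "", names(seqs)),
      sequence = toupper(as.character(seqs))
    ),
    coverage_table = coverage_table
  )
}

#' Attach depths to contig records
#'
#' Core of [read_contigs()], exposed for in-memory use. Every contig must
#' obtain a positive depth from exactly one source; the coverage table, when
#' given, takes precedence over header-encoded values.
#'
#' @param contigs tibble with at least `name` and `sequence` columns.
#' @param coverage_table optional path to a headerless TSV `name<TAB>depth`,
#'   or a data frame with those two columns.
#' @return contig tibble sorted by decreasing length; see [read_contigs()].
#' @export
parse_contig_depths <- function(contigs, coverage_table = NULL) {
  contigs <- as_tibble(contigs)
  spades <- "^NODE_(\\d+)_length_(\\d+)_cov_([0-9.eE+-]+)$"
  hdr_depth <- ifelse(
    grepl(spades, contigs$name),
    suppressWarnings(as.numeric(sub(spades, "\\3", contigs$name))),
    NA_real_
  )
  hdr_name <- ifelse(
    grepl(spades, contigs$name),
    paste0("NODE_", sub(spades, "\\1", contigs$name)),
    contigs$name
  )

  depth <- hdr_depth
  if (!is.null(coverage_table)) {
    tab <- if (is.data.frame(coverage_table)) {
      stats::setNames(as_tibble(coverage_table)[1:2], c("name", "depth"))
    } else {
      utils::read.table(coverage_table, sep = "\t", header = FALSE,
                        col.names = c("name", "depth"),
                        colClasses = c("character", "numeric"))
    }
    hit <- match(hdr_name, tab$name)
    hit2 <- match(contigs$name, tab$name)
    hit[is.na(hit)] <- hit2[is.na(hit)]
    depth <- ifelse(!is.na(hit), tab$depth[hit], depth)
  }

  missing <- hdr_name[is.na(depth)]
  if (length(missing) > 0) {
    abort(paste0("no depth available for contig(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(depth <= 0)) {
    abort(paste0("non-positive depth for contig(s): ",
                 paste(hdr_name[depth <= 0], collapse = ", ")))
  }

  contigs |>
    mutate(
      name = hdr_name,
      sequence = toupper(.data$sequence),
      length = nchar(.data$sequence),
      depth = depth,
      multiplicity = NA_integer_,
      is_unique = NA
    ) |>
    arrange(desc(.data$length), .data$name) |>
    mutate(id = row_number()) |>
    select("id", "name", "sequence", "length", "depth",
           "multiplicity", "is_unique")
}
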