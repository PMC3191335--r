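#' Read EST records from a FASTA file
#'
#' Wraps [Biostrings::readDNAStringSet()] and returns one row per record.
#' Identifiers are the first whitespace-delimited token of each header; the
#' remainder of the header becomes the description. Sequences are uppercased
#' and any IUPAC ambiguity code other than A/C/G/T is normalised to `N`
#' (with a warning).
#'
#' @param path Path to a FASTA file. Sequence lines may be wrapped at any
#'   width; lowercase input is accepted.
#' @return A tibble with columns `seq_id`, `description`, `sequence`,
#'   `length`. An empty file yields an empty tibble with a warning.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1 demo", "acgt", "ACGT"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read FASTA file: ", path))
  empty <- tibble(
    seq_id = character(), description = character(),
    sequence = character(), length = integer()
  )
  if (file.size(path) == 0) {
    warn(paste0("empty FASTA stream: ", path))
    return(empty)
  }
  check_fasta_leader(path)
  set <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(set) == 0) {
    warn(paste0("empty FASTA stream: ", path))
    return(empty)
  }
  headers <- names(set)
  seq_id <- sub("\\s.*$", "", headers)
  description <- ifelse(
    grepl("\\s", headers),
    trimws(sub("^\\S+\\s+", "", headers)),
    ""
  )
  dup <- seq_id[duplicated(seq_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate sequence id in FASTA input: ", dup[1]))
  }
  sequence <- toupper(as.character(set))
  n_amb <- sum(stringr::str_count(sequence, "[^ACGTN]"))
  if (n_amb > 0) {
    warn(sprintf("%d ambiguous IUPAC base(s) normalised to N", n_amb))
    sequence <- gsub("[^ACGTN]", "N", sequence)
  }
  tibble(
    seq_id = seq_id,
    description = description,
    sequence = unname(sequence),
    length = nchar(sequence)
  )
}

# A sequence line before any header can only occur at the top of the file;
# report it with its line number rather than letting the backend fail opaquely.
check_fasta_leader <- function(path) {
  con <- file(path, open = "r")
  on.exit(close(con))
  line_no <- 0L
  repeat {
    chunk <- readLines(con, n = 256L, warn = FALSE)
    if (length(chunk) == 0) return(invisible(TRUE))
    for (ln in chunk) {
      line_no <- line_no + 1L
      if (!nzchar(trimws(ln))) next
      if (startsWith(ln, ">")) return(invisible(TRUE))
      abort(sprintf(
        "FASTA format error: sequence data before any '>' header (line %d)",
        line_no
      ))
    }
  }
}

#' Write EST records to a FASTA file
#'
#' Headers are `">seq_id description"` (description omitted when empty);
#' sequence lines are wrapped at `width` characters. Output re-parses with
#' [read_fasta()] to identical records.
#'
#' @param records A tibble with columns `seq_id`, `sequence` and optionally
#'   `description`.
#' @param path Output file path.
#' @param width Line-wrap width (default 70).
#' @return The input `records`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70) {
  validate_records(records)
  seqs <- Biostrings::DNAStringSet(records$sequence)
  desc <- if ("description" %in% names(records)) records$description else ""
  names(seqs) <- ifelse(
    nzchar(desc), paste(records$seq_id, desc), records$seq_id
  )
  Biostrings::writeXStringSet(seqs, filepath = path, width = width)
  invisible(records)
}

validate_records <- function(records) {
  need <- c("seq_id", "sequence")
  missing <- setdiff(need, names(records))
  if (length(missing) > 0) {
    abort(paste0("records are missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(records$seq_id)) {
    abort(paste0("duplicate seq_id: ",
                 records$seq_id[duplicated(records$seq_id)][1]))
  }
  bad <- grepl("[^ACGTN]", records$sequence)
  if (any(bad)) {
    abort(paste0("sequence contains characters outside {A,C,G,T,N}: ",
                 records$seq_id[bad][1]))
  }
  invisible(records)
}

#' Write a table of SSR loci as TSV
#'
#' Columns: `seq_id`, `motif`, `class_label`, `period`, `repeat_count`,
#' `start`, `end`, `span_length`; rows ordered by `seq_id` then `start`.
#'
#' @param loci A loci tibble as returned by [find_ssrs()].
#' @param path Output file path.
#' @return The written tibble, invisibly.
#' @export
write_loci_table <- function(loci, path) {
  cols <- c("seq_id", "motif", "class_label", "period", "repeat_count",
            "start", "end", "span_length")
  out <- loci |>
    arrange(.data$seq_id, .data$start) |>
    select(dplyr::all_of(cols))
  readr::write_tsv(out, path)
  invisible(out)
}
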