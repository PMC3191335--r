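#' Trim terminal poly-A/poly-T tracts
#'
#' EST reads frequently end in poly-A (or, on the opposite strand, poly-T)
#' tails left by the cDNA library construction. This removes them so that no
#' A or T homopolymer of length >= `window` intersects the first or last
#' `window` bases of any sequence. An offending run must *start* within the
#' terminal `window` bases (5' end; mirrored at the 3' end) to trigger
#' trimming, and trimming always removes a whole prefix/suffix through the
#' run, never an internal splice. The rule is applied iteratively, so stacked
#' tails (e.g. `...AAAAAAAAAACGTTTTTTTTTT`) are fully removed, while genuine
#' internal mononucleotide repeats are untouched. G/C homopolymers are never
#' trimmed.
#'
#' @param records A records tibble (see [read_fasta()]).
#' @param window Homopolymer length threshold and terminal window size
#'   (default 10).
#' @return The records tibble with `sequence` and `length` updated. Records
#'   trimmed to length zero are retained with an empty sequence; callers
#'   (e.g. [run_pipeline()]) decide whether to drop them.
#' @examples
#' recs <- tibble::tibble(
#'   seq_id = "s1", description = "",
#'   sequence = "AAAAAAAAAAAAGTTCGTTCGTTCGTAC", length = 28L
#' )
#' trim_poly_tails(recs)$sequence
#' @export
trim_poly_tails <- function(records, window = 10) {
  if (window < 2) abort("window must be >= 2")
  validate_records(records)
  records |>
    mutate(
      sequence = vapply(.data$sequence, trim_one, character(1),
                        window = window, USE.NAMES = FALSE),
      length = nchar(.data$sequence)
    )
}

trim_one <- function(seq, window) {
  repeat {
    L <- nchar(seq)
    if (L == 0) return("")
    r <- rle(as_chars(seq))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    offending <- r$values %in% c("A", "T") & r$lengths >= window
    five <- offending & starts <= window
    three <- offending & ends >= L - window + 1L
    if (any(five)) {
      seq <- substr(seq, max(ends[five]) + 1L, L)
    } else if (any(three)) {
      seq <- substr(seq, 1L, min(starts[three]) - 1L)
    } else {
      return(seq)
    }
  }
}

#' Base composition of a set of sequences
#'
#' Exact integer counts over all sequences plus reporting percentages at one
#' decimal (rounding mode configurable to match either half-up or truncating
#' report styles).
#'
#' @param records A records tibble.
#' @param rounding `"half_up"` (default) or `"truncate"`.
#' @return A list of class `"composition_stats"`: counts per base (`count_A`
#'   ... `count_N`), `total_bases`, `at_sum`, `gc_sum`, percentages
#'   (`pct_A`, `pct_C`, `pct_G`, `pct_T`, `pct_N`, `pct_AT`, `pct_GC`),
#'   `n_sequences` and `mean_length`.
#' @examples
#' composition_stats(tibble::tibble(seq_id = "s", sequence = "AATTGGCC"))
#' @export
composition_stats <- function(records, rounding = c("half_up", "truncate")) {
  rounding <- match.arg(rounding)
  if (nrow(records) == 0) abort("no sequences")
  counts <- vapply(
    c("A", "C", "G", "T", "N"),
    function(b) sum(stringr::str_count(records$sequence, stringr::fixed(b))),
    numeric(1)
  )
  total <- sum(nchar(records$sequence))
  if (sum(counts) != total) abort("sequences contain non-ACGTN characters")
  pct <- function(x) round_fixed(100 * x / total, 1, rounding)
  out <- list(
    count_A = counts[["A"]], count_C = counts[["C"]],
    count_G = counts[["G"]], count_T = counts[["T"]],
    count_N = counts[["N"]],
    total_bases = total,
    at_sum = counts[["A"]] + counts[["T"]],
    gc_sum = counts[["G"]] + counts[["C"]],
    pct_A = pct(counts[["A"]]), pct_C = pct(counts[["C"]]),
    pct_G = pct(counts[["G"]]), pct_T = pct(counts[["T"]]),
    pct_N = pct(counts[["N"]]),
    pct_AT = pct(counts[["A"]] + counts[["T"]]),
    pct_GC = pct(counts[["G"]] + counts[["C"]]),
    n_sequences = nrow(records),
    mean_length = total / nrow(records)
  )
  structure(out, class = "composition_stats")
}

#' @export
print.composition_stats <- function(x, ...) {
  cat(sprintf(
    "Composition over %d sequences (%s bases, mean length %.1f bp)\n",
    x$n_sequences, format(x$total_bases, big.mark = ","), x$mean_length
  ))
  cat(sprintf("  A %.1f%%  C %.1f%%  G %.1f%%  T %.1f%%  N %.1f%%\n",
              x$pct_A, x$pct_C, x$pct_G, x$pct_T, x$pct_N))
  cat(sprintf("  A+T %.1f%%  G+C %.1f%%\n", x$pct_AT, x$pct_GC))
  invisible(x)
}
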