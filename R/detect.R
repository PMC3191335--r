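#' Detection settings for perfect SSR search
#'
#' Defaults reflect common EST-SSR survey practice: motifs of period 2-6
#' repeated at least five times. Mononucleotide runs can be included by
#' setting `min_period = 1`, but are excluded from the default catalogue
#' (mono runs are dominated by sequencing poly-A/T artefacts).
#'
#' @param min_period Smallest motif length searched (default 2).
#' @param max_period Largest motif length searched (default 6).
#' @param min_repeats Minimum number of complete motif copies (default 5).
#' @return A list of class `"detection_config"`.
#' @export
detection_config <- function(min_period = 2, max_period = 6, min_repeats = 5) {
  if (!(min_period >= 1 && min_period <= max_period && max_period <= 6)) {
    abort("need 1 <= min_period <= max_period <= 6")
  }
  if (min_repeats < 2) abort("min_repeats must be >= 2")
  structure(
    list(
      min_period = as.integer(min_period),
      max_period = as.integer(max_period),
      min_repeats = as.integer(min_repeats)
    ),
    class = "detection_config"
  )
}

#' Primitive (non-decomposable) form of a motif
#'
#' The shortest string whose tandem repetition equals the input: `"ATAT"`
#' reduces to `"AT"`, `"AAAAAA"` to `"A"`, `"ACG"` is already primitive.
#' Needed so a locus is reported once at its true period — `(AT)6` must never
#' additionally surface as `(ATAT)3`.
#'
#' @param motif A single DNA string over A/C/G/T.
#' @return The primitive motif.
#' @export
primitive_motif <- function(motif) {
  if (length(motif) != 1 || !nzchar(motif)) abort("motif must be one non-empty string")
  if (grepl("[^ACGT]", motif)) abort("motif must contain only A/C/G/T (no N)")
  n <- nchar(motif)
  for (d in seq_len(n)) {
    if (n %% d != 0) next
    unit <- substr(motif, 1, d)
    if (strrep(unit, n %/% d) == motif) return(unit)
  }
  motif
}

#' Reporting class of an SSR motif
#'
#' Dinucleotide motifs are reported jointly with their base-wise complement
#' (A<->T, C<->G, no reversal), the lexicographically smaller motif first:
#' `"GA"` belongs to class `"CT/GA"`. Exactly six dinucleotide classes exist
#' among primitive motifs (AC/TG, AG/TC, AT/TA, CA/GT, CG/GC, CT/GA). Motifs
#' of other periods are their own class label.
#'
#' @param motif A primitive DNA motif of period 1-6 (vectorised).
#' @return A tibble with columns `motif`, `class_label`, `period`,
#'   `period_class`.
#' @examples
#' classify_motif(c("GA", "TTC"))
#' @export
classify_motif <- function(motif) {
  period <- nchar(motif)
  if (any(period < 1 | period > 6)) abort("motif period must be 1..6")
  prim <- vapply(motif, primitive_motif, character(1), USE.NAMES = FALSE)
  if (any(prim != motif)) {
    abort(paste0("motif is not primitive: ", motif[prim != motif][1]))
  }
  comp <- complement(motif)
  label <- ifelse(
    period == 2,
    paste(pmin(motif, comp), pmax(motif, comp), sep = "/"),
    motif
  )
  tibble(
    motif = motif,
    class_label = label,
    period = as.integer(period),
    period_class = period_class_name(period)
  )
}

#' Find all maximal perfect SSRs
#'
#' Scans every sequence for maximal perfect tandem repeats whose primitive
#' motif period lies in `[min_period, max_period]` and which contain at least
#' `min_repeats` complete motif copies. Only complete units count: the
#' reported span starts at the run's first base and covers
#' `floor(run_length / period)` copies; trailing partial units are excluded.
#' `N` never matches, so runs are split around ambiguous bases. Loci whose
#' motif is non-primitive at the scanned period are suppressed (they are
#' reported at their primitive period instead). Scanning is strand-asymmetric:
#' only the deposited strand is searched.
#'
#' @param records A records tibble.
#' @param config A [detection_config()].
#' @return A loci tibble: `seq_id`, `motif`, `class_label`, `period`,
#'   `period_class`, `repeat_count`, `start`, `end`, `span_length`
#'   (1-based inclusive coordinates), ordered by record, then `start`, then
#'   `period`.
#' @examples
#' recs <- tibble::tibble(seq_id = "s1", sequence = "GGACACACACACATT")
#' find_ssrs(recs)
#' @export
find_ssrs <- function(records, config = detection_config()) {
  validate_records(records)
  stopifnot(inherits(config, "detection_config"))
  hits <- purrr::map2(
    records$sequence, records$seq_id,
    function(s, id) find_ssrs_one(s, id, config)
  )
  loci <- bind_rows(hits)
  if (nrow(loci) == 0) {
    return(tibble(
      seq_id = character(), motif = character(), class_label = character(),
      period = integer(), period_class = character(),
      repeat_count = integer(), start = integer(), end = integer(),
      span_length = integer()
    ))
  }
  cls <- classify_motif(loci$motif)
  loci$class_label <- cls$class_label
  loci$period_class <- cls$period_class
  loci[, c("seq_id", "motif", "class_label", "period", "period_class",
           "repeat_count", "start", "end", "span_length")]
}

# Core scan: for period p, positions where s[i] == s[i+p] (both unambiguous)
# form runs; a run of k such matches is a perfectly periodic region of
# k + p bases.
find_ssrs_one <- function(seq, seq_id, config) {
  L <- nchar(seq)
  min_rep <- config$min_repeats
  if (L < config$min_period * min_rep) return(NULL)
  ch <- as_chars(seq)
  valid <- ch %in% DNA_BASES
  out <- vector("list", 0L)
  for (p in config$min_period:config$max_period) {
    n <- L - p
    need <- p * (min_rep - 1L)            # matches needed for min_rep units
    if (n < need) next
    eq <- ch[seq_len(n)] == ch[(p + 1L):L] &
      valid[seq_len(n)] & valid[(p + 1L):L]
    r <- rle(eq)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    keep <- which(r$values & r$lengths >= need)
    for (idx in keep) {
      i0 <- run_start[idx]
      count <- (r$lengths[idx] + p) %/% p
      motif <- substr(seq, i0, i0 + p - 1L)
      if (nchar(primitive_motif(motif)) != p) next
      out[[length(out) + 1L]] <- list(
        seq_id = seq_id, motif = motif, period = p,
        repeat_count = as.integer(count),
        start = as.integer(i0),
        end = as.integer(i0 + count * p - 1L),
        span_length = as.integer(count * p)
      )
    }
  }
  if (length(out) == 0) return(NULL)
  res <- bind_rows(out)
  res[order(res$start, res$period), ]
}
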