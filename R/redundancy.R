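#' Remove duplicate and contained sequences
#'
#' Sequences are clustered whenever one is identical to, or an exact
#' substring of, another (transitive closure, given strand only, no
#' mismatches). From each cluster the longest sequence is retained, ties
#' broken by input order. This is a deterministic stand-in for
#' BLAST-self-search + manual alignment redundancy screens: near-identical
#' homologs with mismatches are not merged.
#'
#' @param records A records tibble.
#' @return The kept records (input order preserved) with a redundancy report
#'   attached as attribute `"redundancy"`; retrieve it with
#'   [redundancy_report()]. The report holds `n_input`, `n_kept`,
#'   `n_dropped_duplicate` and a `clusters` tibble
#'   (`representative`, `member`).
#' @examples
#' recs <- tibble::tibble(
#'   seq_id = c("a", "b", "c"),
#'   sequence = c("ACGTACGTAAGG", "ACGTACGTAAGG", "ACGTACGT")
#' )
#' kept <- dedupe_records(recs)
#' redundancy_report(kept)
#' @export
dedupe_records <- function(records) {
  validate_records(records)
  n <- nrow(records)
  seqs <- records$sequence
  lens <- nchar(seqs)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  # identical sequences
  for (grp in split(seq_len(n), seqs)) {
    if (length(grp) > 1) for (j in grp[-1]) union_(grp[1], j)
  }
  # strict containment: check each sequence against all strictly longer ones
  if (n > 1) {
    first_of_seq <- !duplicated(seqs)
    for (i in which(first_of_seq)) {
      longer <- which(lens > lens[i])
      if (length(longer) == 0) next
      hit <- longer[stringi::stri_detect_fixed(seqs[longer], seqs[i])]
      for (j in hit) union_(i, j)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  clusters <- split(seq_len(n), root)
  rep_idx <- vapply(clusters, function(m) m[which.max(lens[m])], integer(1))
  kept <- sort(rep_idx)
  cluster_tbl <- bind_rows(purrr::map2(
    unname(rep_idx), unname(clusters),
    function(r, m) tibble(
      representative = records$seq_id[r],
      member = records$seq_id[m]
    )
  ))
  out <- records[kept, , drop = FALSE]
  report <- list(
    n_input = n,
    n_kept = length(kept),
    n_dropped_duplicate = n - length(kept),
    clusters = cluster_tbl
  )
  attr(out, "redundancy") <- report
  out
}

#' Discard sequences that are pure repeat with no flanks
#'
#' A sequence is dropped when the union of its detected SSR spans covers the
#' whole sequence: with no unique flanking bases its identity cannot be
#' established and no primer can be placed. Records with no detected locus
#' are always kept (the rule only applies to SSR-composed sequences).
#'
#' @param records A records tibble.
#' @param loci Loci detected on these records ([find_ssrs()]).
#' @return Kept records with a report (fields `n_input`, `n_kept`,
#'   `n_dropped_flankless`, `dropped_ids`) attached as attribute
#'   `"redundancy"`.
#' @export
drop_flankless <- function(records, loci) {
  validate_records(records)
  unknown <- setdiff(unique(loci$seq_id), records$seq_id)
  if (length(unknown) > 0) {
    abort(paste0("loci reference unknown seq_id: ", unknown[1]))
  }
  cov <- loci |>
    group_by(.data$seq_id) |>
    summarise(covered = union_span_length(.data$start, .data$end)) |>
    left_join(records[, c("seq_id", "length")], by = "seq_id")
  flankless_ids <- cov$seq_id[cov$covered >= cov$length]
  out <- records[!records$seq_id %in% flankless_ids, , drop = FALSE]
  attr(out, "redundancy") <- list(
    n_input = nrow(records),
    n_kept = nrow(out),
    n_dropped_flankless = length(flankless_ids),
    dropped_ids = flankless_ids
  )
  out
}

#' Extract the redundancy report attached by a filtering step
#'
#' @param records Output of [dedupe_records()] or [drop_flankless()].
#' @return The report list, or `NULL` if none is attached.
#' @export
redundancy_report <- function(records) attr(records, "redundancy")
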