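#' SSR frequency as a percentage of sequences
#'
#' `100 * n_ssrs / n_ests`, reported at one decimal.
#'
#' @param n_ssrs Number of SSR loci.
#' @param n_ests Number of sequences surveyed (> 0).
#' @param rounding `"half_up"` (default) or `"truncate"`.
#' @return Percentage at one decimal.
#' @examples
#' frequency_percent(1499, 42784) # 3.5
#' @export
frequency_percent <- function(n_ssrs, n_ests, rounding = "half_up") {
  if (n_ests <= 0) abort("n_ests must be > 0")
  round_fixed(100 * n_ssrs / n_ests, 1, rounding)
}

#' SSR density: bases surveyed per SSR
#'
#' @param total_bases Total bases surveyed.
#' @param n_ssrs Number of SSR loci (> 0; density of zero loci is undefined).
#' @return A list with `bp` (exact bases per SSR) and `kb` (kilobases at one
#'   decimal), or `NULL` when `n_ssrs` is 0.
#' @examples
#' density_bp_per_ssr(23384661, 1499) # one SSR every ~15.6 kb
#' @export
density_bp_per_ssr <- function(total_bases, n_ssrs, rounding = "half_up") {
  if (n_ssrs == 0) return(NULL)
  bp <- total_bases / n_ssrs
  list(bp = bp, kb = round_fixed(bp / 1000, 1, rounding))
}

#' Catalogue statistics for a set of detected SSRs
#'
#' Computes the headline numbers of an EST-SSR survey: SSR frequency
#' (loci per 100 sequences), density (bases per SSR), fraction of bases
#' inside repeat spans (overlaps counted once), counts and percentages per
#' period class, per motif class within each period class, a raw-motif
#' dinucleotide table, the repeat-count histogram, and the number of
#' sequences carrying more than one locus. All counting is exact; only the
#' reported percentages are rounded.
#'
#' @param records The analysed records tibble.
#' @param loci Loci detected on these records.
#' @param min_repeats Detection threshold the loci were called with (used
#'   only for validation/reporting; default 5).
#' @param rounding `"half_up"` (default) or `"truncate"`.
#' @param total_bases Basis for density/span statistics. Defaults to the
#'   total length of `records` ("analyzed" basis); pass the pre-filter total
#'   for a "raw" basis.
#' @return An object of class `"ssr_catalogue"`; see [tidy.ssr_catalogue()],
#'   [glance.ssr_catalogue()] and [autoplot.ssr_catalogue()].
#' @export
summarize_catalogue <- function(records, loci, min_repeats = 5,
                                rounding = c("half_up", "truncate"),
                                total_bases = NULL) {
  rounding <- match.arg(rounding)
  validate_records(records)
  unknown <- setdiff(unique(loci$seq_id), records$seq_id)
  if (length(unknown) > 0) {
    abort(paste0("loci reference unknown seq_id: ", unknown[1]))
  }
  n_ests <- nrow(records)
  n_ssrs <- nrow(loci)
  total_bases <- total_bases %||% sum(records$length)
  rnd <- function(x, d = 1) round_fixed(x, d, rounding)

  covered <- if (n_ssrs > 0) {
    loci |>
      group_by(.data$seq_id) |>
      summarise(covered = union_span_length(.data$start, .data$end)) |>
      (\(d) sum(d$covered))()
  } else 0L

  per_period <- loci |>
    count(.data$period_class, name = "count") |>
    mutate(pct = rnd(100 * .data$count / n_ssrs))
  per_motif_class <- loci |>
    count(.data$period_class, .data$class_label, name = "count") |>
    group_by(.data$period_class) |>
    mutate(pct = rnd(100 * .data$count / sum(.data$count))) |>
    ungroup() |>
    arrange(.data$period_class, dplyr::desc(.data$count), .data$class_label)
  per_motif_raw_di <- loci |>
    filter(.data$period == 2L) |>
    count(.data$motif, name = "count") |>
    arrange(dplyr::desc(.data$count), .data$motif)
  hist_tbl <- loci |>
    count(.data$repeat_count, name = "count") |>
    arrange(.data$repeat_count)
  density <- density_bp_per_ssr(total_bases, n_ssrs, rounding)

  structure(list(
    n_ests = n_ests,
    total_bases = total_bases,
    n_ssrs = n_ssrs,
    frequency_pct = frequency_percent(n_ssrs, n_ests, rounding),
    density_bp_per_ssr = if (is.null(density)) NA_real_ else density$bp,
    density_kb_per_ssr = if (is.null(density)) NA_real_ else density$kb,
    span_fraction_pct = rnd(100 * covered / total_bases, 3),
    per_period = per_period,
    per_motif_class = per_motif_class,
    per_motif_raw_di = per_motif_raw_di,
    repeat_count_hist = hist_tbl,
    min_repeat_count = if (n_ssrs > 0) min(loci$repeat_count) else NA_integer_,
    max_repeat_count = if (n_ssrs > 0) max(loci$repeat_count) else NA_integer_,
    n_multi_ssr_ests = sum(table(loci$seq_id) >= 2),
    min_repeats = min_repeats,
    rounding = rounding
  ), class = "ssr_catalogue")
}

#' @export
print.ssr_catalogue <- function(x, ...) {
  cat(sprintf(
    "SSR catalogue: %d loci in %d sequences (%s bases)\n",
    x$n_ssrs, x$n_ests, format(x$total_bases, big.mark = ",")
  ))
  cat(sprintf("  frequency: %.1f%% of sequences\n", x$frequency_pct))
  if (!is.na(x$density_kb_per_ssr)) {
    cat(sprintf("  density:   one SSR every %.1f kb\n", x$density_kb_per_ssr))
  }
  cat(sprintf("  repeat spans: %.3f%% of bases\n", x$span_fraction_pct))
  if (x$n_ssrs > 0) {
    cat(sprintf("  repeat counts: %d-%d; sequences with >1 SSR: %d\n",
                x$min_repeat_count, x$max_repeat_count, x$n_multi_ssr_ests))
    pp <- x$per_period
    cat("  per period class: ",
        paste(sprintf("%s %d (%.1f%%)", pp$period_class, pp$count, pp$pct),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Tidy the per-motif table of an SSR catalogue
#'
#' @param x An `"ssr_catalogue"`.
#' @param ... Unused.
#' @return A tibble with one row per motif class: `period_class`,
#'   `class_label`, `count`, `pct` (percentage within the period class).
#' @method tidy ssr_catalogue
#' @export
tidy.ssr_catalogue <- function(x, ...) x$per_motif_class

#' One-row summary of an SSR catalogue
#'
#' @param x An `"ssr_catalogue"`.
#' @param ... Unused.
#' @return A one-row tibble of the headline statistics.
#' @method glance ssr_catalogue
#' @export
glance.ssr_catalogue <- function(x, ...) {
  tibble(
    n_ests = x$n_ests,
    total_bases = x$total_bases,
    n_ssrs = x$n_ssrs,
    frequency_pct = x$frequency_pct,
    density_kb_per_ssr = x$density_kb_per_ssr,
    span_fraction_pct = x$span_fraction_pct,
    min_repeat_count = x$min_repeat_count,
    max_repeat_count = x$max_repeat_count,
    n_multi_ssr_ests = x$n_multi_ssr_ests
  )
}

#' Plot an SSR catalogue
#'
#' @param object An `"ssr_catalogue"`.
#' @param type `"period"` (distribution over period classes), `"motif"`
#'   (motif classes within period classes) or `"repeat_count"` (repeat-length
#'   histogram).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ssr_catalogue
#' @export
autoplot.ssr_catalogue <- function(object,
                                   type = c("period", "motif", "repeat_count"),
                                   ...) {
  type <- match.arg(type)
  if (type == "period") {
    ggplot2::ggplot(object$per_period,
                    ggplot2::aes(x = .data$period_class, y = .data$count)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", .data$pct)),
                         vjust = -0.4, size = 3) +
      ggplot2::labs(x = "repeat type", y = "number of SSRs",
                    title = "SSRs by motif period")
  } else if (type == "motif") {
    ggplot2::ggplot(object$per_motif_class,
                    ggplot2::aes(x = stats::reorder(.data$class_label,
                                                    -.data$count),
                                 y = .data$count)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::facet_wrap(~period_class, scales = "free_x") +
      ggplot2::labs(x = "motif class", y = "number of SSRs",
                    title = "Motif frequency within period classes") +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
  } else {
    ggplot2::ggplot(object$repeat_count_hist,
                    ggplot2::aes(x = .data$repeat_count, y = .data$count)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(x = "repeat count", y = "number of SSRs",
                    title = "Repeat-count distribution")
  }
}

# serialisable plain-list view (tibbles -> data frames for jsonlite)
catalogue_as_list <- function(x) {
  lapply(unclass(x), function(el) if (inherits(el, "tbl_df")) as.data.frame(el) else el)
}
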