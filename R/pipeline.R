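#' Run the full EST-SSR mining pipeline
#'
#' Executes trim -> detect -> drop flankless -> deduplicate -> re-detect on
#' the kept set -> summarise -> design primers, and writes the run artifacts
#' (`loci.tsv`, `summary.json`, `markers.tsv`, `redundancy.tsv`,
#' `config.json`) to `outdir`. Per-stage counts are logged to standard error
#' and always reconcile: input = kept + dropped at every filter.
#'
#' Deduplication runs after detection and flankless filtering by default;
#' `dedup_first = TRUE` swaps the order for sensitivity checks.
#'
#' @param input Path to a FASTA file, or a records tibble.
#' @param outdir Output directory (created if missing); `NULL` writes nothing.
#' @param detection A [detection_config()].
#' @param constraints A [primer_constraints()].
#' @param window Poly-A/T trimming window (default 10).
#' @param rounding Percentage rounding mode, `"half_up"` or `"truncate"`.
#' @param density_basis `"analyzed"` (default; bases of the post-trim,
#'   post-redundancy set feed the density) or `"raw"` (post-trim total
#'   before redundancy filtering).
#' @param dedup_first Deduplicate before detection/flankless filtering.
#' @param design Design primers for the catalogued loci (default TRUE).
#' @param max_candidates Primer pairs kept per locus (default 3).
#' @param tm_method Melting-temperature model, see [melt_tm()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list: `records` (analysed set), `loci`, `summary`
#'   (an `"ssr_catalogue"`), `candidates`, `markers`, `redundancy` (stage
#'   counts and clusters), `config` (fully resolved settings).
#' @export
run_pipeline <- function(input, outdir = NULL,
                         detection = detection_config(),
                         constraints = primer_constraints(),
                         window = 10,
                         rounding = c("half_up", "truncate"),
                         density_basis = c("analyzed", "raw"),
                         dedup_first = FALSE,
                         design = TRUE,
                         max_candidates = 3,
                         tm_method = "breslauer",
                         quiet = FALSE) {
  rounding <- match.arg(rounding)
  density_basis <- match.arg(density_basis)
  say <- function(...) if (!quiet) inform(sprintf(...))

  records <- if (is.character(input)) read_fasta(input) else as_tibble(input)
  validate_records(records)
  n_in <- nrow(records)
  say("input: %d sequences", n_in)

  trimmed <- trim_poly_tails(records, window = window)
  n_empty <- sum(trimmed$length == 0)
  trimmed <- filter(trimmed, .data$length > 0)
  if (nrow(trimmed) == 0) abort("no sequences survived trimming")
  say("trimming: %d kept, %d emptied and dropped", nrow(trimmed), n_empty)
  raw_total <- sum(trimmed$length)

  if (dedup_first) {
    trimmed <- dedupe_records(trimmed)
    dedup_rep <- redundancy_report(trimmed)
    say("deduplication: %d kept, %d dropped",
        dedup_rep$n_kept, dedup_rep$n_dropped_duplicate)
  }

  loci_all <- find_ssrs(trimmed, detection)
  say("detection: %d loci in %d sequences",
      nrow(loci_all), dplyr::n_distinct(loci_all$seq_id))

  flanked <- drop_flankless(trimmed, loci_all)
  flank_rep <- redundancy_report(flanked)
  say("flankless filter: %d kept, %d dropped",
      flank_rep$n_kept, flank_rep$n_dropped_flankless)

  if (!dedup_first) {
    kept <- dedupe_records(flanked)
    dedup_rep <- redundancy_report(kept)
    say("deduplication: %d kept, %d dropped",
        dedup_rep$n_kept, dedup_rep$n_dropped_duplicate)
  } else {
    kept <- flanked
  }

  loci <- loci_all |> filter(.data$seq_id %in% kept$seq_id)
  total_bases <- if (density_basis == "raw") raw_total else sum(kept$length)
  summary <- summarize_catalogue(
    kept, loci, min_repeats = detection$min_repeats,
    rounding = rounding, total_bases = total_bases
  )
  say("catalogue: %d loci, frequency %.1f%%", summary$n_ssrs,
      summary$frequency_pct)

  candidates <- NULL
  markers <- NULL
  skipped <- NULL
  if (design && nrow(loci) > 0) {
    candidates <- design_primers(kept, loci, constraints,
                                 max_candidates = max_candidates,
                                 tm_method = tm_method)
    skipped <- attr(candidates, "skipped")
    markers <- marker_sheet(candidates)
    say("primer design: %d loci designable, %d skipped",
        nrow(markers), if (is.null(skipped)) 0L else nrow(skipped))
  }

  redundancy <- list(
    n_input = n_in,
    n_dropped_empty = n_empty,
    n_dropped_flankless = flank_rep$n_dropped_flankless,
    n_dropped_duplicate = dedup_rep$n_dropped_duplicate,
    n_kept = nrow(kept),
    flankless_ids = flank_rep$dropped_ids,
    clusters = dedup_rep$clusters
  )
  config <- list(
    window = window, rounding = rounding, density_basis = density_basis,
    dedup_first = dedup_first, tm_method = tm_method,
    max_candidates = max_candidates,
    detection = unclass(detection), constraints = unclass(constraints)
  )

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_loci_table(loci, file.path(outdir, "loci.tsv"))
    jsonlite::write_json(
      list(composition = unclass(composition_stats(kept, rounding)),
           catalogue = catalogue_as_list(summary),
           redundancy = redundancy[setdiff(names(redundancy), "clusters")]),
      file.path(outdir, "summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    if (!is.null(markers)) {
      readr::write_tsv(markers, file.path(outdir, "markers.tsv"))
    }
    clusters <- redundancy$clusters |>
      mutate(dropped_flankless = .data$member %in% redundancy$flankless_ids)
    readr::write_tsv(clusters, file.path(outdir, "redundancy.tsv"))
    jsonlite::write_json(config, file.path(outdir, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    say("artifacts written to %s", outdir)
  }

  invisible(list(
    records = kept, loci = loci, summary = summary,
    candidates = candidates, markers = markers, skipped = skipped,
    redundancy = redundancy, config = config
  ))
}
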