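#' Parameters for the synthetic EST generator
#'
#' Defaults emulate a normalized insect EST library: mean read length 469 bp
#' (SD 150, truncated at 100), slight A/T bias (28/22/22/28), 3.5% of reads
#' carrying one planted SSR, and a period mix of 67/31.1/1.5/0.4% for
#' periods 2/3/4/5 (the renormalised distribution observed in EST-SSR
#' surveys). Corruption rates (duplicates, contained prefixes, terminal
#' poly-A/T tails) are library-preparation artefacts; flankless records are
#' pure-repeat reads with no unique sequence.
#'
#' @param n_sequences Number of base (uncorrupted) sequences.
#' @param mean_length,sd_length Length model (normal, truncated at 100 bp).
#' @param base_probs Named probabilities for A, C, G, T (must sum to 1).
#' @param ssr_rate Fraction of base sequences with one planted SSR.
#' @param period_mix Named distribution over periods `"2"`-`"5"`.
#' @param repeat_count_range Inclusive range of planted repeat counts.
#' @param dup_rate Fraction of base records copied verbatim under a new id.
#' @param containment_rate Fraction of base records from which a strict
#'   prefix copy is added.
#' @param flankless_rate Fraction (of `n_sequences`) of added pure-repeat
#'   records with no flanks.
#' @param tail_rate Fraction of base records given a terminal poly-A/T tail
#'   (length 12-30; always removable by [trim_poly_tails()]).
#' @param seed Mandatory integer seed.
#' @return A list of class `"sim_params"`.
#' @export
sim_params <- function(n_sequences,
                       mean_length = 469, sd_length = 150,
                       base_probs = c(A = 0.28, C = 0.22, G = 0.22, T = 0.28),
                       ssr_rate = 0.035,
                       period_mix = c(`2` = 0.67, `3` = 0.311,
                                      `4` = 0.015, `5` = 0.004),
                       repeat_count_range = c(5, 16),
                       dup_rate = 0.02, containment_rate = 0.01,
                       flankless_rate = 0.005, tail_rate = 0.15,
                       seed) {
  if (missing(seed)) abort("seed is mandatory")
  if (abs(sum(base_probs) - 1) > 1e-8) abort("base_probs must sum to 1")
  if (!setequal(names(base_probs), DNA_BASES)) {
    abort("base_probs must be named A, C, G, T")
  }
  if (abs(sum(period_mix) - 1) > 1e-8) abort("period_mix must sum to 1")
  rates <- c(dup_rate, containment_rate, flankless_rate, tail_rate)
  if (any(rates < 0 | rates > 1)) abort("rates must be in [0, 1]")
  # duplicate/containment/tail corruptions pick disjoint base records
  if (dup_rate + containment_rate + tail_rate > 1) {
    abort("dup_rate + containment_rate + tail_rate must not exceed 1")
  }
  if (repeat_count_range[1] < 2) abort("repeat counts below 2 are not repeats")
  structure(as.list(environment()), class = "sim_params")
}

#' Insert a perfect SSR into a background sequence
#'
#' Inserts `motif` repeated `repeat_count` times so that the repeat occupies
#' positions `position .. position + period*repeat_count - 1` of the result.
#' The bases immediately adjacent to the inserted run are rewritten when they
#' would extend the run in phase, guaranteeing the planted run is maximal at
#' its own period.
#'
#' @param background DNA string.
#' @param motif Primitive motif (A/C/G/T).
#' @param repeat_count Number of copies (>= 2).
#' @param position 1-based insertion point; at least one background base must
#'   remain on each side (`2 <= position <= nchar(background)`).
#' @return The sequence with the repeat planted.
#' @examples
#' plant_ssr(strrep("G", 30), "AT", 5, 10)
#' @export
plant_ssr <- function(background, motif, repeat_count, position) {
  if (primitive_motif(motif) != motif) {
    abort(paste0("motif is not primitive: ", motif))
  }
  L <- nchar(background)
  p <- nchar(motif)
  if (position < 2 || position > L) {
    abort("position must leave at least one background base on each side")
  }
  run <- strrep(motif, repeat_count)
  left <- substr(background, 1, position - 1)
  right <- substr(background, position, L)
  # break in-phase extension at both junctions
  ext_left <- substr(motif, p, p)
  if (substr(left, nchar(left), nchar(left)) == ext_left) {
    repl <- setdiff(DNA_BASES, ext_left)[1]
    substr(left, nchar(left), nchar(left)) <- repl
  }
  ext_right <- substr(motif, 1, 1)
  if (substr(right, 1, 1) == ext_right) {
    repl <- setdiff(DNA_BASES, ext_right)[1]
    substr(right, 1, 1) <- repl
  }
  paste0(left, run, right)
}

random_seq <- function(len, probs) {
  paste(sample(DNA_BASES, len, replace = TRUE, prob = probs[DNA_BASES]),
        collapse = "")
}

random_primitive_motif <- function(period) {
  repeat {
    m <- paste(sample(DNA_BASES, period, replace = TRUE), collapse = "")
    if (primitive_motif(m) == m) return(m)
  }
}

#' Simulate an EST-like dataset with exhaustive ground truth
#'
#' Generates background reads from the base-composition model, plants perfect
#' SSRs with at least 25 bp of clean flank on each side, then appends
#' duplicate copies, contained prefix copies and flankless pure-repeat
#' records and adds terminal poly-A/T tails, all at the configured rates.
#' Every emitted repeat — planted or incidental — is recorded in the truth:
#' after planting, the detector is run on each base sequence; a background is
#' re-rolled if the planted locus is not recovered exactly (e.g. an
#' incidental repeat abuts it in phase), and all other detected loci are
#' recorded as incidental truth. Backgrounds are also re-rolled until they
#' are stable under [trim_poly_tails()], so planted coordinates survive
#' trimming unchanged (5'-tail offsets are recorded separately).
#'
#' @param params A [sim_params()].
#' @param config The [detection_config()] the truth is enumerated with.
#' @return A list with `records` (tibble ready for [write_fasta()]) and
#'   `truth`, a list holding: `loci` (tibble: `seq_id`, `motif`, `period`,
#'   `repeat_count`, `start` on the emitted sequence, `start_core` on the
#'   trim-stable core, `end_core`, `planted`), `duplicate_pairs`,
#'   `flankless_ids`, `tailed` and `per_class_counts` (truth loci per motif
#'   class over the base records — what a trim/detect/filter pipeline should
#'   recover).
#' @export
simulate_est_set <- function(params, config = detection_config()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n <- params$n_sequences
  probs <- params$base_probs
  lens <- pmax(100L, as.integer(round(rnorm(n, params$mean_length,
                                            params$sd_length))))
  carrier <- runif(n) < params$ssr_rate
  periods <- as.integer(names(params$period_mix))

  seqs <- character(n)
  truth_loci <- vector("list", n)
  for (i in seq_len(n)) {
    plant <- NULL
    if (carrier[i]) {
      p <- sample(periods, 1, prob = params$period_mix)
      motif <- random_primitive_motif(p)
      count <- sample(params$repeat_count_range[1]:params$repeat_count_range[2], 1)
      span <- p * count
      lens[i] <- max(lens[i], span + 60L)
      plant <- list(motif = motif, count = count, span = span)
    }
    for (try in 1:50) {
      bg <- random_seq(lens[i], probs)
      if (trim_one(bg, 10) != bg) next
      if (is.null(plant)) {
        seqs[i] <- bg
        det <- find_ssrs_one(bg, paste0("EST", i), config)
        if (!is.null(det)) truth_loci[[i]] <- mutate(det, planted = FALSE)
        break
      }
      pos <- sample(26:(lens[i] - 24L), 1)
      planted_seq <- plant_ssr(bg, plant$motif, plant$count, pos)
      if (trim_one(planted_seq, 10) != planted_seq) next
      det <- find_ssrs_one(planted_seq, paste0("EST", i), config)
      hit <- !is.null(det) &&
        any(det$motif == plant$motif & det$repeat_count == plant$count &
              det$start == pos)
      if (!hit) next
      overlap <- det$start <= (pos + plant$span - 1L) &
        det$end >= pos & !(det$start == pos & det$motif == plant$motif &
                             det$repeat_count == plant$count)
      if (any(overlap)) next
      seqs[i] <- planted_seq
      truth_loci[[i]] <- det |>
        mutate(planted = .data$start == pos & .data$motif == plant$motif &
                 .data$repeat_count == plant$count)
      break
    }
    if (!nzchar(seqs[i])) {
      abort(sprintf("could not place a clean SSR in sequence %d after 50 tries", i))
    }
  }

  records <- tibble(
    seq_id = paste0("EST", seq_len(n)),
    description = ifelse(carrier, "synthetic EST (SSR planted)",
                         "synthetic EST"),
    sequence = seqs,
    length = nchar(seqs)
  )
  loci <- bind_rows(truth_loci)
  if (nrow(loci) > 0) {
    loci <- loci |>
      mutate(start_core = .data$start, end_core = .data$end) |>
      select("seq_id", "motif", "period", "repeat_count",
             "start", "start_core", "end_core", "planted")
  } else {
    loci <- tibble(seq_id = character(), motif = character(),
                   period = integer(), repeat_count = integer(),
                   start = integer(), start_core = integer(),
                   end_core = integer(), planted = logical())
  }

  # disjoint corruption assignments over base records
  n_dup <- round(n * params$dup_rate)
  n_con <- round(n * params$containment_rate)
  n_tail <- round(n * params$tail_rate)
  picks <- sample(n, n_dup + n_con + n_tail)
  dup_src <- picks[seq_len(n_dup)]
  con_src <- picks[n_dup + seq_len(n_con)]
  tail_ids <- picks[n_dup + n_con + seq_len(n_tail)]

  extra <- list()
  duplicate_pairs <- list()
  # terminal tails on existing base records (applied before copies are taken
  # so duplicates/prefixes derive from the untailed core by construction)
  tailed <- NULL
  if (n_tail > 0) {
    tail_end <- sample(c("5prime", "3prime"), n_tail, replace = TRUE)
    tail_base <- sample(c("A", "T"), n_tail, replace = TRUE)
    tail_len <- sample(12:30, n_tail, replace = TRUE)
    for (k in seq_len(n_tail)) {
      i <- tail_ids[k]
      s <- records$sequence[i]
      # junction base must differ from the tail base or trimming would eat
      # into the core
      if (tail_end[k] == "3prime") {
        if (substr(s, nchar(s), nchar(s)) == tail_base[k]) {
          tail_base[k] <- setdiff(c("A", "T"), tail_base[k])
        }
        if (substr(s, nchar(s), nchar(s)) == tail_base[k]) {
          tail_end[k] <- "5prime"   # unreachable, defensive
        }
        records$sequence[i] <- paste0(s, strrep(tail_base[k], tail_len[k]))
      }
      if (tail_end[k] == "5prime") {
        if (substr(s, 1, 1) == tail_base[k]) {
          tail_base[k] <- setdiff(c("A", "T"), tail_base[k])
        }
        records$sequence[i] <- paste0(strrep(tail_base[k], tail_len[k]), s)
        sel <- loci$seq_id == records$seq_id[i]
        loci$start[sel] <- loci$start[sel] + tail_len[k]
      }
    }
    records$length <- nchar(records$sequence)
    tailed <- tibble(seq_id = records$seq_id[tail_ids],
                     tail_end = tail_end, tail_base = tail_base,
                     tail_len = as.integer(tail_len))
  }

  for (k in seq_along(dup_src)) {
    i <- dup_src[k]
    extra[[length(extra) + 1L]] <- tibble(
      seq_id = paste0(records$seq_id[i], "_dup"),
      description = "exact duplicate",
      sequence = records$sequence[i],
      length = records$length[i]
    )
    duplicate_pairs[[length(duplicate_pairs) + 1L]] <- tibble(
      original = records$seq_id[i],
      copy = paste0(records$seq_id[i], "_dup"),
      relation = "identical"
    )
  }
  for (k in seq_along(con_src)) {
    i <- con_src[k]
    cut <- max(50L, as.integer(floor(records$length[i] * runif(1, 0.4, 0.8))))
    cut <- min(cut, records$length[i] - 1L)
    extra[[length(extra) + 1L]] <- tibble(
      seq_id = paste0(records$seq_id[i], "_part"),
      description = "contained prefix copy",
      sequence = substr(records$sequence[i], 1, cut),
      length = cut
    )
    duplicate_pairs[[length(duplicate_pairs) + 1L]] <- tibble(
      original = records$seq_id[i],
      copy = paste0(records$seq_id[i], "_part"),
      relation = "contained"
    )
  }

  n_flank <- round(n * params$flankless_rate)
  flankless_ids <- character(0)
  for (k in seq_len(n_flank)) {
    p <- sample(periods, 1, prob = params$period_mix)
    motif <- random_primitive_motif(p)
    count <- sample(max(params$repeat_count_range[1], config$min_repeats):
                      params$repeat_count_range[2], 1)
    id <- sprintf("FLK%d", k)
    extra[[length(extra) + 1L]] <- tibble(
      seq_id = id, description = "pure repeat, no flanks",
      sequence = strrep(motif, count), length = nchar(motif) * count
    )
    flankless_ids <- c(flankless_ids, id)
  }

  records <- bind_rows(records, bind_rows(extra))
  cls <- if (nrow(loci) > 0) classify_motif(loci$motif) else NULL
  per_class <- if (nrow(loci) > 0) {
    loci |>
      mutate(class_label = cls$class_label, period_class = cls$period_class) |>
      count(.data$period_class, .data$class_label, name = "count")
  } else {
    tibble(period_class = character(), class_label = character(),
           count = integer())
  }

  list(
    records = records,
    truth = list(
      loci = loci,
      duplicate_pairs = bind_rows(duplicate_pairs),
      flankless_ids = flankless_ids,
      tailed = tailed,
      per_class_counts = per_class
    )
  )
}
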