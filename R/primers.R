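#' PRIMER3-style constraints for SSR-flanking primer design
#'
#' Defaults mirror a typical EST-SSR marker screen: primer length 18-27
#' bases, calculated Tm 55-60 degrees C, amplicon 100-300 bp, GC 30-70%
#' with 50% optimum.
#'
#' @param len_min,len_max Primer length bounds (bases).
#' @param tm_min,tm_max Calculated melting-temperature bounds (degrees C).
#' @param product_min,product_max Amplicon size bounds (bases).
#' @param gc_min,gc_max,gc_opt GC-content bounds and optimum (percent).
#' @param max_self_comp Maximum tolerated ungapped self/pair-complementary
#'   stretch (bases, default 8).
#' @param max_3prime_comp Maximum complementary stretch anchored at a 3'
#'   terminus (bases, default 4).
#' @param min_flank Minimum flank length on each side of the repeat for a
#'   locus to be designable (default `len_min`).
#' @return A list of class `"primer_constraints"`.
#' @export
primer_constraints <- function(len_min = 18, len_max = 27,
                               tm_min = 55, tm_max = 60,
                               product_min = 100, product_max = 300,
                               gc_min = 30, gc_max = 70, gc_opt = 50,
                               max_self_comp = 8, max_3prime_comp = 4,
                               min_flank = len_min) {
  if (!(len_min <= len_max)) abort("len_min must be <= len_max")
  if (!(product_min <= product_max)) abort("product_min must be <= product_max")
  if (!(gc_min <= gc_opt && gc_opt <= gc_max)) {
    abort("need gc_min <= gc_opt <= gc_max")
  }
  structure(as.list(environment()), class = "primer_constraints")
}

#' GC content of DNA strings
#'
#' @param seq Character vector of non-empty A/C/G/T strings (N is an error:
#'   an ambiguous base cannot be scored).
#' @param digits Reporting precision (default one decimal, half-up).
#' @return Percent G+C.
#' @examples
#' gc_percent("AGTTCCGCCACATCCATTC") # 52.6
#' @export
gc_percent <- function(seq, digits = 1) {
  if (any(!nzchar(seq))) abort("empty sequence")
  if (any(grepl("[^ACGT]", seq))) abort("sequence must contain only A/C/G/T")
  round_fixed(100 * stringr::str_count(seq, "[GC]") / nchar(seq), digits)
}

# Nearest-neighbor tables, 5'->3' dinucleotide keyed.
# "breslauer": Breslauer et al. 1986, as used by classic PRIMER3/oligotm
# (initiation dS -10.8 cal/K, Schildkraut-Lifson 16.6*log10[Na+] correction).
# "santalucia": unified Allawi & SantaLucia parameters with terminal
# initiation terms and the 0.368*N*ln[Na+] entropy correction.
NN_TABLES <- list(
  breslauer = list(
    dH = c(AA = -9.1, TT = -9.1, AT = -8.6, TA = -6.0, CA = -5.8, TG = -5.8,
           GT = -6.5, AC = -6.5, CT = -7.8, AG = -7.8, GA = -5.6, TC = -5.6,
           CG = -11.9, GC = -11.1, GG = -11.0, CC = -11.0),
    dS = c(AA = -24.0, TT = -24.0, AT = -23.9, TA = -16.9, CA = -12.9,
           TG = -12.9, GT = -17.3, AC = -17.3, CT = -20.8, AG = -20.8,
           GA = -13.5, TC = -13.5, CG = -27.8, GC = -26.7, GG = -26.6,
           CC = -26.6)
  ),
  santalucia = list(
    dH = c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, TG = -8.5,
           GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0),
    dS = c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
           TG = -22.7, GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0,
           GA = -22.2, TC = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           CC = -19.9)
  )
)

#' Oligonucleotide melting temperature
#'
#' Nearest-neighbor thermodynamic Tm. The default, `"breslauer"`, is the
#' classic PRIMER3/oligotm model (Breslauer 1986 table, -10.8 cal/K helix
#' initiation entropy, total-strand concentration divided by four, and the
#' Schildkraut-Lifson `16.6*log10[Na+]` salt correction). `"santalucia"`
#' uses the unified SantaLucia parameters with terminal initiation terms and
#' the `0.368*N*ln[Na+]` entropy salt correction. `"wallace"` is the 2(A+T)
#' + 4(G+C) rule. Model and conditions are recorded as attributes of the
#' result.
#'
#' @param seq Character vector of A/C/G/T strings, each at least 8 bases
#'   (any length for `"wallace"` is still rejected below 8, keeping one
#'   contract for all methods).
#' @param method `"breslauer"` (default), `"santalucia"` or `"wallace"`.
#' @param conc_nM Total oligo concentration in nM (default 50).
#' @param na_mM Monovalent cation concentration in mM (default 50).
#' @return Numeric vector of Tm in degrees C, with attributes `method`,
#'   `conc_nM`, `na_mM`.
#' @examples
#' melt_tm("AGTTCCGCCACATCCATTC")            # ~60.9
#' melt_tm(strrep("AT", 5), method = "wallace")
#' @export
melt_tm <- function(seq, method = c("breslauer", "santalucia", "wallace"),
                    conc_nM = 50, na_mM = 50) {
  method <- match.arg(method)
  if (any(nchar(seq) < 8)) abort("sequence must be at least 8 bases for Tm")
  if (any(grepl("[^ACGT]", seq))) abort("sequence must contain only A/C/G/T")
  na <- na_mM / 1000
  ct <- conc_nM * 1e-9
  R <- 1.9872
  tm <- if (method == "wallace") {
    at <- stringr::str_count(seq, "[AT]")
    gc <- stringr::str_count(seq, "[GC]")
    2 * at + 4 * gc
  } else {
    tab <- NN_TABLES[[method]]
    vapply(seq, function(s) {
      ch <- as_chars(s)
      L <- length(ch)
      din <- paste0(ch[-L], ch[-1])
      dh <- sum(tab$dH[din])
      ds <- sum(tab$dS[din])
      if (method == "breslauer") {
        ds <- ds - 10.8
        dh * 1000 / (ds + R * log(ct / 4)) - 273.15 + 16.6 * log10(na)
      } else {
        for (term in ch[c(1, L)]) {
          if (term %in% c("G", "C")) {
            dh <- dh + 0.1; ds <- ds - 2.8
          } else {
            dh <- dh + 2.3; ds <- ds + 4.1
          }
        }
        ds <- ds + 0.368 * (L - 1) * log(na)
        dh * 1000 / (ds + R * log(ct / 4)) - 273.15
      }
    }, numeric(1), USE.NAMES = FALSE)
  }
  attr(tm, "method") <- method
  attr(tm, "conc_nM") <- conc_nM
  attr(tm, "na_mM") <- na_mM
  tm
}

all_kmers <- function(s, k) {
  L <- nchar(s)
  if (L < k) return(character(0))
  substring(s, 1:(L - k + 1), k:L)
}

# threshold checks equivalent to lcs_substring(x, y) <= max_any and
# three-prime stretch <= max3: a complementary stretch longer than t exists
# iff a common (t+1)-mer exists (and, for the 3' anchor, iff the (t+1)-suffix
# occurs). Much cheaper than computing the full score during enumeration.
pair_comp_ok <- function(a, b, rc_a, rc_b, max_any, max3) {
  k <- max_any + 1L
  if (any(all_kmers(a, k) %in% all_kmers(rc_b, k))) return(FALSE)
  sa <- substr(a, nchar(a) - max3, nchar(a))
  if (stringi::stri_detect_fixed(rc_b, sa)) return(FALSE)
  sb <- substr(b, nchar(b) - max3, nchar(b))
  !stringi::stri_detect_fixed(rc_a, sb)
}

# longest common substring length between two strings (ungapped, all offsets)
lcs_substring <- function(x, y) {
  a <- as_chars(x); b <- as_chars(y)
  la <- length(a); lb <- length(b)
  best <- 0L
  for (off in (-(lb - 1L)):(la - 1L)) {
    i <- max(1L, off + 1L):min(la, lb + off)
    m <- a[i] == b[i - off]
    if (!any(m)) next
    r <- rle(m)
    best <- max(best, max(r$lengths[r$values]))
  }
  best
}

# longest suffix of x occurring as a substring of y
longest_suffix_in <- function(x, y) {
  L <- nchar(x)
  k <- 0L
  for (len in seq_len(L)) {
    suf <- substr(x, L - len + 1L, L)
    if (!stringi::stri_detect_fixed(y, suf)) break
    k <- len
  }
  k
}

#' Complementarity between two primers
#'
#' `any_comp` is the longest ungapped complementary (antiparallel) stretch
#' between the two oligos over every alignment offset — equivalently the
#' longest common substring of `fw` and the reverse complement of `rv`.
#' `three_prime_comp` is the longest such stretch anchored at the 3'
#' terminus of either primer. Self-complementarity is
#' `complementarity_scores(x, x)`.
#'
#' @param fw,rv Primer sequences (A/C/G/T strings).
#' @return A list with integer fields `any_comp` and `three_prime_comp`.
#' @examples
#' complementarity_scores("AAAA", "TTTT")$any_comp # 4
#' @export
complementarity_scores <- function(fw, rv) {
  if (any(grepl("[^ACGT]", c(fw, rv)))) abort("primers must be A/C/G/T only")
  rc_rv <- revcomp(rv)
  rc_fw <- revcomp(fw)
  list(
    any_comp = as.integer(lcs_substring(fw, rc_rv)),
    three_prime_comp = as.integer(max(
      longest_suffix_in(fw, rc_rv),
      longest_suffix_in(rv, rc_fw)
    ))
  )
}

#' Design SSR-flanking primer pairs
#'
#' For each locus, enumerates every forward primer in the 5' flank and every
#' reverse primer (reverse-complemented) in the 3' flank over all allowed
#' lengths and positions; primers may not overlap *any* detected SSR of the
#' same sequence (repeat-anchored priming is never acceptable for a
#' microsatellite marker). Single primers are filtered by length, GC, Tm and
#' self-complementarity; pairs by product size and pair complementarity.
#' Surviving pairs are scored with
#' `penalty = |fw_tm - rv_tm| + (|fw_gc - gc_opt| + |rv_gc - gc_opt|)/100`
#' and returned in ascending penalty order (ties: leftmost `fw_start`, then
#' smallest product). Pair complementarity is evaluated lazily in penalty
#' order and enumeration stops after `max_candidates` accepted pairs per
#' locus, keeping the search tractable; all other filters are exhaustive.
#'
#' @param records Records tibble.
#' @param loci Loci to design for (rows of a [find_ssrs()] result). All loci
#'   of a sequence, designable or not, are used as exclusion zones.
#' @param constraints A [primer_constraints()].
#' @param max_candidates Maximum returned pairs per locus (default 5).
#' @param tm_method Melting-temperature model, see [melt_tm()].
#' @return A tibble of candidates: locus columns (`seq_id`, `motif`,
#'   `repeat_count`, `start`, `end`), `fw_seq`, `rv_seq`, `fw_start`,
#'   `rv_end`, `product_size`, `fw_tm`, `rv_tm`, `fw_gc`, `rv_gc`,
#'   `penalty`. Loci yielding no candidate are listed in the attribute
#'   `"skipped"` (`seq_id`, `start`, `reason`), with reason
#'   `"insufficient flank"` when a flank cannot hold a primer.
#' @export
design_primers <- function(records, loci,
                           constraints = primer_constraints(),
                           max_candidates = 5,
                           tm_method = "breslauer") {
  validate_records(records)
  stopifnot(inherits(constraints, "primer_constraints"))
  seq_by_id <- setNames(records$sequence, records$seq_id)
  unknown <- setdiff(unique(loci$seq_id), names(seq_by_id))
  if (length(unknown) > 0) {
    abort(paste0("loci reference unknown seq_id: ", unknown[1]))
  }
  out <- vector("list", nrow(loci))
  skipped <- list()
  for (i in seq_len(nrow(loci))) {
    locus <- loci[i, ]
    blocked <- loci[loci$seq_id == locus$seq_id, c("start", "end")]
    res <- design_one(seq_by_id[[locus$seq_id]], locus, blocked,
                      constraints, max_candidates, tm_method)
    if (is.character(res)) {
      skipped[[length(skipped) + 1L]] <-
        tibble(seq_id = locus$seq_id, start = locus$start, reason = res)
    } else {
      out[[i]] <- res
    }
  }
  result <- bind_rows(out)
  if (nrow(result) == 0) {
    result <- tibble(
      seq_id = character(), motif = character(), repeat_count = integer(),
      start = integer(), end = integer(), fw_seq = character(),
      rv_seq = character(), fw_start = integer(), rv_end = integer(),
      product_size = integer(), fw_tm = numeric(), rv_tm = numeric(),
      fw_gc = numeric(), rv_gc = numeric(), penalty = numeric()
    )
  }
  attr(result, "skipped") <- bind_rows(skipped)
  result
}

design_one <- function(seq, locus, blocked, cons, max_candidates, tm_method) {
  L <- nchar(seq)
  if (locus$start < 1 || locus$end > L) {
    abort(paste0("locus coordinates outside record ", locus$seq_id))
  }
  left_len <- locus$start - 1L
  right_len <- L - locus$end
  if (left_len < cons$min_flank || right_len < cons$min_flank) {
    return("insufficient flank")
  }
  fw <- enumerate_primers(seq, 1L, locus$start - 1L, blocked, cons,
                          tm_method, reverse = FALSE)
  if (nrow(fw) == 0) return("no acceptable forward primer")
  rv <- enumerate_primers(seq, locus$end + 1L, L, blocked, cons,
                          tm_method, reverse = TRUE)
  if (nrow(rv) == 0) return("no acceptable reverse primer")
  pairs <- cross_join(
    rename(fw, fw_seq = "pseq", fw_start = "win_start",
           fw_tm = "tm", fw_gc = "gc") |> select(-"win_end"),
    rename(rv, rv_seq = "pseq", rv_end = "win_end",
           rv_tm = "tm", rv_gc = "gc") |> select(-"win_start")
  ) |>
    mutate(product_size = .data$rv_end - .data$fw_start + 1L) |>
    filter(.data$product_size >= cons$product_min,
           .data$product_size <= cons$product_max) |>
    mutate(penalty = abs(.data$fw_tm - .data$rv_tm) +
             (abs(.data$fw_gc - cons$gc_opt) +
                abs(.data$rv_gc - cons$gc_opt)) / 100) |>
    arrange(.data$penalty, .data$fw_start, .data$product_size)
  if (nrow(pairs) == 0) return("no pair within product-size bounds")
  accepted <- integer(0)
  rc_fw <- revcomp(pairs$fw_seq)
  rc_rv <- revcomp(pairs$rv_seq)
  for (j in seq_len(nrow(pairs))) {
    if (pair_comp_ok(pairs$fw_seq[j], pairs$rv_seq[j], rc_fw[j], rc_rv[j],
                     cons$max_self_comp, cons$max_3prime_comp)) {
      accepted <- c(accepted, j)
      if (length(accepted) >= max_candidates) break
    }
  }
  if (length(accepted) == 0) return("no pair passed complementarity checks")
  pairs[accepted, ] |>
    mutate(
      seq_id = locus$seq_id, motif = locus$motif,
      repeat_count = locus$repeat_count,
      start = locus$start, end = locus$end,
      .before = 1
    )
}

# all windows of allowed length inside [lo, hi] not intersecting any blocked
# span, filtered by N content, GC, Tm and self-complementarity
enumerate_primers <- function(seq, lo, hi, blocked, cons, tm_method, reverse) {
  if (hi - lo + 1L < cons$len_min) {
    return(tibble(pseq = character(), win_start = integer(),
                  win_end = integer(), tm = numeric(), gc = numeric()))
  }
  wins <- purrr::map(cons$len_min:cons$len_max, function(len) {
    if (hi - len + 1L < lo) return(NULL)
    s <- lo:(hi - len + 1L)
    tibble(win_start = s, win_end = s + len - 1L)
  }) |> bind_rows()
  keep <- rep(TRUE, nrow(wins))
  for (k in seq_len(nrow(blocked))) {
    keep <- keep & !(wins$win_start <= blocked$end[k] &
                       wins$win_end >= blocked$start[k])
  }
  wins <- wins[keep, ]
  if (nrow(wins) == 0) return(tibble(pseq = character(), win_start = integer(),
                                     win_end = integer(), tm = numeric(),
                                     gc = numeric()))
  tmpl <- substring(seq, wins$win_start, wins$win_end)
  ok <- !grepl("N", tmpl, fixed = TRUE)
  wins <- wins[ok, ]; tmpl <- tmpl[ok]
  if (length(tmpl) == 0) return(tibble(pseq = character(),
                                       win_start = integer(),
                                       win_end = integer(), tm = numeric(),
                                       gc = numeric()))
  pseq <- if (reverse) revcomp(tmpl) else tmpl
  gc <- 100 * stringr::str_count(pseq, "[GC]") / nchar(pseq)
  ok <- gc >= cons$gc_min & gc <= cons$gc_max
  wins <- wins[ok, ]; pseq <- pseq[ok]; gc <- gc[ok]
  if (length(pseq) == 0) return(tibble(pseq = character(),
                                       win_start = integer(),
                                       win_end = integer(), tm = numeric(),
                                       gc = numeric()))
  tm <- as.numeric(melt_tm(pseq, method = tm_method))
  ok <- tm >= cons$tm_min & tm <= cons$tm_max
  wins <- wins[ok, ]; pseq <- pseq[ok]; gc <- gc[ok]; tm <- tm[ok]
  if (length(pseq) > 0) {
    rc <- revcomp(pseq)
    ok <- vapply(seq_along(pseq), function(i) {
      pair_comp_ok(pseq[i], pseq[i], rc[i], rc[i],
                   cons$max_self_comp, cons$max_3prime_comp)
    }, logical(1))
    wins <- wins[ok, ]; pseq <- pseq[ok]; gc <- gc[ok]; tm <- tm[ok]
  }
  tibble(pseq = pseq, win_start = wins$win_start, win_end = wins$win_end,
         tm = tm, gc = gc)
}

#' Build a marker sheet from primer candidates
#'
#' Keeps the best (lowest-penalty) pair per locus and formats the columns of
#' a typical marker table: marker name, source sequence, SSR in "(CA)15"
#' notation, product size, primer sequences and melting temperatures.
#'
#' @param candidates Output of [design_primers()].
#' @param prefix Marker name prefix (default `"MK"`).
#' @return A tibble with one row per designable locus.
#' @export
marker_sheet <- function(candidates, prefix = "MK") {
  if (nrow(candidates) == 0) {
    return(tibble(name = character(), seq_id = character(), ssr = character(),
                  product_size = integer(), fw_primer = character(),
                  fw_tm = numeric(), rv_primer = character(),
                  rv_tm = numeric()))
  }
  best <- candidates |>
    group_by(.data$seq_id, .data$start) |>
    dplyr::slice_min(.data$penalty, n = 1, with_ties = FALSE) |>
    ungroup() |>
    arrange(.data$seq_id, .data$start)
  tibble(
    name = sprintf("%s%03d", prefix, seq_len(nrow(best))),
    seq_id = best$seq_id,
    ssr = ssr_notation(best$motif, best$repeat_count),
    product_size = best$product_size,
    fw_primer = best$fw_seq,
    fw_tm = round_fixed(best$fw_tm, 1),
    rv_primer = best$rv_seq,
    rv_tm = round_fixed(best$rv_tm, 1)
  )
}
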