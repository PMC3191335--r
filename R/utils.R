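DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised over `x`. `N` is its own complement; only `A`, `C`, `G`, `T`,
#' `N` are accepted.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("ACGTT")
#' @export
revcomp <- function(x) {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    abort(paste0("revcomp(): non-ACGTN characters in input: ", x[bad][1]))
  }
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", x))
}

complement <- function(x) chartr("ACGTN", "TGCAN", x)

#' Round at a fixed precision with an explicit rounding mode
#'
#' `"half_up"` rounds 0.05 upward (the convention used for all reported
#' percentages); `"truncate"` drops digits beyond the precision. Base R's
#' `round()` (banker's rounding) is deliberately not used for reported
#' percentages.
#'
#' @param x Numeric vector.
#' @param digits Decimal digits to keep.
#' @param mode `"half_up"` or `"truncate"`.
#' @return Rounded numeric vector.
#' @examples
#' round_fixed(3.504, 1)            # 3.5
#' round_fixed(31.15, 1, "truncate") # 31.1
#' @export
round_fixed <- function(x, digits = 1, mode = c("half_up", "truncate")) {
  mode <- match.arg(mode)
  p <- 10^digits
  # epsilon guards against binary representation of exact .x5 values
  eps <- 1e-9
  if (mode == "half_up") {
    sign(x) * floor(abs(x) * p + 0.5 + eps) / p
  } else {
    sign(x) * floor(abs(x) * p + eps) / p
  }
}

# total length of the union of 1-based inclusive intervals
union_span_length <- function(start, end) {
  if (length(start) == 0L) return(0L)
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  total <- 0L
  cur_s <- start[1]; cur_e <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= cur_e + 1L) {
      cur_e <- max(cur_e, end[i])
    } else {
      total <- total + (cur_e - cur_s + 1L)
      cur_s <- start[i]; cur_e <- end[i]
    }
  }
  total + (cur_e - cur_s + 1L)
}

as_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

#' Format an SSR in "(CA)15" notation
#'
#' @param motif Character vector of motifs.
#' @param repeat_count Integer vector of repeat counts.
#' @return Character vector like `"(CA)15"`.
#' @export
ssr_notation <- function(motif, repeat_count) {
  sprintf("(%s)%d", motif, as.integer(repeat_count))
}

#' Parse "(CA)15"-style SSR notation
#'
#' @param x Character vector like `"(CA)15"`.
#' @return A tibble with columns `motif`, `repeat_count`, `period`,
#'   `period_class`.
#' @examples
#' parse_ssr_notation(c("(CA)15", "(TTTA)8"))
#' @export
parse_ssr_notation <- function(x) {
  m <- stringr::str_match(trimws(x), "^\\(([ACGTacgt]+)\\)\\s*(\\d+)$")
  if (anyNA(m[, 1])) {
    abort(paste0("cannot parse SSR notation: ", x[is.na(m[, 1])][1]))
  }
  motif <- toupper(m[, 2])
  tibble(
    motif = motif,
    repeat_count = as.integer(m[, 3]),
    period = nchar(motif),
    period_class = period_class_name(nchar(motif))
  )
}

period_class_name <- function(period) {
  cls <- c("mono", "di", "tri", "tetra", "penta", "hexa")
  if (any(period < 1 | period > 6)) abort("period must be in 1..6")
  cls[period]
}
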