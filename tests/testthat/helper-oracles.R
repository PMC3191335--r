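# Independent oracles used to cross-check the implementation. These follow
# deliberately different algorithms from the package code paths.

# Brute-force perfect-SSR finder: for every period and every start position,
# extend unit by unit with substring comparisons; keep runs with enough
# complete units, drop non-left-maximal starts and non-primitive motifs.
oracle_find_ssrs <- function(seq, min_period = 2, max_period = 6,
                             min_repeats = 5) {
  L <- nchar(seq)
  rows <- list()
  for (p in min_period:max_period) {
    i <- 1L
    while (i + p - 1L <= L) {
      motif <- substr(seq, i, i + p - 1L)
      if (grepl("N", motif, fixed = TRUE)) { i <- i + 1L; next }
      # left-maximality: the previous base must not continue the run in phase
      if (i > 1L) {
        prev <- substr(seq, i - 1L, i - 1L)
        inphase <- substr(seq, i + p - 1L, i + p - 1L)
        if (prev != "N" && prev == inphase) { i <- i + 1L; next }
      }
      units <- 1L
      while (i + (units + 1L) * p - 1L <= L &&
             substr(seq, i + units * p, i + (units + 1L) * p - 1L) == motif) {
        units <- units + 1L
      }
      if (units >= min_repeats && oracle_is_primitive(motif)) {
        rows[[length(rows) + 1L]] <- data.frame(
          motif = motif, period = p, repeat_count = units,
          start = i, end = i + units * p - 1L
        )
      }
      i <- i + 1L
    }
  }
  if (length(rows) == 0) {
    return(data.frame(motif = character(), period = integer(),
                      repeat_count = integer(), start = integer(),
                      end = integer()))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$period), , drop = FALSE]
}

# primitivity via the regex engine (backreference repetition), a different
# mechanism from the package's divisor scan
oracle_is_primitive <- function(motif) {
  n <- nchar(motif)
  if (n == 1) return(TRUE)
  for (d in seq_len(n - 1)) {
    if (grepl(sprintf("^(.{%d})\\1+$", d), motif)) return(FALSE)
  }
  TRUE
}

oracle_primitive_motif <- function(motif) {
  n <- nchar(motif)
  for (d in seq_len(n)) {
    if (grepl(sprintf("^(.{%d})\\1*$", d), motif)) return(substr(motif, 1, d))
  }
  motif
}

# full dynamic-programming longest common substring (vs the package's
# offset-scan) for complementarity cross-checks
oracle_lcs <- function(x, y) {
  a <- strsplit(x, "")[[1]]; b <- strsplit(y, "")[[1]]
  best <- 0L
  prev <- integer(length(b))
  for (i in seq_along(a)) {
    cur <- integer(length(b))
    for (j in seq_along(b)) {
      if (a[i] == b[j]) {
        cur[j] <- if (j == 1) 1L else prev[j - 1] + 1L
        best <- max(best, cur[j])
      }
    }
    prev <- cur
  }
  best
}

oracle_revcomp <- function(x) {
  paste(rev(chartr("ACGTN", "TGCAN", strsplit(x, "")[[1]])), collapse = "")
}

# independent re-check of every primer-design constraint on emitted candidates
validate_candidates <- function(cands, records, loci, cons,
                                tm_method = "breslauer") {
  seq_by_id <- setNames(records$sequence, records$seq_id)
  for (k in seq_len(nrow(cands))) {
    row <- cands[k, ]
    tmpl <- seq_by_id[[row$seq_id]]
    fl <- nchar(row$fw_seq); rl <- nchar(row$rv_seq)
    expect_true(fl >= cons$len_min && fl <= cons$len_max)
    expect_true(rl >= cons$len_min && rl <= cons$len_max)
    # sequences match their stated template coordinates
    expect_identical(substr(tmpl, row$fw_start, row$fw_start + fl - 1),
                     row$fw_seq)
    expect_identical(oracle_revcomp(substr(tmpl, row$rv_end - rl + 1,
                                           row$rv_end)),
                     row$rv_seq)
    expect_identical(row$product_size, row$rv_end - row$fw_start + 1L)
    expect_true(row$product_size >= cons$product_min &&
                  row$product_size <= cons$product_max)
    # GC recomputed by character counting
    for (s in c(row$fw_seq, row$rv_seq)) {
      gc <- 100 * sum(strsplit(s, "")[[1]] %in% c("G", "C")) / nchar(s)
      expect_true(gc >= cons$gc_min && gc <= cons$gc_max)
    }
    expect_true(row$fw_tm >= cons$tm_min - 1 && row$fw_tm <= cons$tm_max + 1)
    expect_true(row$rv_tm >= cons$tm_min - 1 && row$rv_tm <= cons$tm_max + 1)
    # neither primer touches any detected SSR of the same sequence
    spans <- loci[loci$seq_id == row$seq_id, ]
    fw_rng <- c(row$fw_start, row$fw_start + fl - 1)
    rv_rng <- c(row$rv_end - rl + 1, row$rv_end)
    for (j in seq_len(nrow(spans))) {
      expect_false(fw_rng[1] <= spans$end[j] && fw_rng[2] >= spans$start[j])
      expect_false(rv_rng[1] <= spans$end[j] && rv_rng[2] >= spans$start[j])
    }
    # complementarity via the DP oracle
    expect_true(oracle_lcs(row$fw_seq, oracle_revcomp(row$fw_seq)) <=
                  cons$max_self_comp)
    expect_true(oracle_lcs(row$rv_seq, oracle_revcomp(row$rv_seq)) <=
                  cons$max_self_comp)
    expect_true(oracle_lcs(row$fw_seq, oracle_revcomp(row$rv_seq)) <=
                  cons$max_self_comp)
  }
  invisible(TRUE)
}

no_terminal_run <- function(seq, window = 10) {
  L <- nchar(seq)
  if (L == 0) return(TRUE)
  r <- rle(strsplit(seq, "")[[1]])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  bad <- r$values %in% c("A", "T") & r$lengths >= window &
    (starts <= window | ends >= L - window + 1)
  !any(bad)
}

make_records <- function(...) {
  seqs <- c(...)
  ids <- names(seqs) %||% paste0("s", seq_along(seqs))
  tibble::tibble(
    seq_id = ids, description = "",
    sequence = unname(seqs), length = nchar(unname(seqs))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_dna <- function(n, probs = c(A = 0.28, C = 0.22, G = 0.22, T = 0.28)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

table2_path <- function() {
  system.file("extdata", "table2_markers.tsv", package = "estssr",
              mustWork = TRUE)
}
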