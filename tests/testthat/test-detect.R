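test_that("primitive_motif agrees with a regex-based oracle on all motifs up to length 6", {
  for (len in 1:6) {
    motifs <- apply(
      expand.grid(rep(list(c("A", "C", "G", "T")), len)), 1, paste,
      collapse = ""
    )
    got <- vapply(motifs, primitive_motif, character(1), USE.NAMES = FALSE)
    want <- vapply(motifs, oracle_primitive_motif, character(1),
                   USE.NAMES = FALSE)
    expect_identical(got, want)
  }
  expect_identical(primitive_motif("ATAT"), "AT")
  expect_identical(primitive_motif("ACG"), "ACG")
  expect_identical(primitive_motif("AAAAAA"), "A")
  expect_error(primitive_motif("AN"), "N")
})

test_that("motif classification pairs dinucleotides with their complements", {
  cls <- classify_motif(c("GA", "AG", "TTC", "TTTA", "A", "AATTG"))
  expect_equal(cls$class_label,
               c("CT/GA", "AG/TC", "TTC", "TTTA", "A", "AATTG"))
  expect_equal(cls$period_class, c("di", "di", "tri", "tetra", "mono", "penta"))
  # exactly six labels across all primitive dinucleotides
  dis <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T")),
               1, paste, collapse = "")
  dis <- dis[vapply(dis, oracle_is_primitive, logical(1))]
  expect_setequal(unique(classify_motif(dis)$class_label),
                  c("AC/TG", "AG/TC", "AT/TA", "CA/GT", "CG/GC", "CT/GA"))
  expect_error(classify_motif("ATAT"), "not primitive")
})

test_that("worked detection examples", {
  expect_equal(nrow(find_ssrs(make_records(x = "ACGTACG"))), 0L)

  one <- find_ssrs(make_records(x = "GGACACACACACATT"))
  expect_equal(one$motif, "AC")
  expect_equal(one$repeat_count, 5L)
  expect_equal(c(one$start, one$end), c(3L, 12L))

  # four copies stay below the five-repeat threshold
  expect_equal(nrow(find_ssrs(make_records(x = "TTGCAGAGAGAGGCTT"))), 0L)

  long <- find_ssrs(make_records(x = "CCTCTCTCTCTCTCTCTCTCTCTCTCTCTCTCTCC"))
  expect_equal(nrow(long), 1L)
  expect_equal(long$repeat_count, 16L)

  split <- find_ssrs(make_records(x = "ATATATATATNATATATATAT"))
  expect_equal(nrow(split), 2L)
  expect_equal(split$repeat_count, c(5L, 5L))
  expect_equal(split$motif, c("AT", "AT"))
})

test_that("a locus is reported once, at its primitive period only", {
  hits <- find_ssrs(make_records(x = paste0("GGC", strrep("AT", 10), "CGG")),
                    detection_config(2, 6, 5))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$period, 2L)
  # mononucleotide runs appear only when min_period = 1
  mono <- make_records(x = paste0("GCGTC", strrep("A", 8), "GCGTC"))
  expect_equal(nrow(find_ssrs(mono)), 0L)
  withmono <- find_ssrs(mono, detection_config(1, 6, 5))
  expect_equal(withmono$motif, "A")
  expect_equal(withmono$repeat_count, 8L)
})

test_that("detector equals the brute-force oracle on random sequences", {
  set.seed(101)
  for (i in 1:120) {
    # seed motifs into random background to raise the hit rate
    seq <- random_dna(sample(80:300, 1))
    if (i %% 2 == 0) {
      m <- sample(c("AT", "AG", "TTC", "CAG", "TTTA", "AATTG"), 1)
      k <- sample(4:9, 1)
      pos <- sample(nchar(seq) - 2, 1) + 1
      seq <- paste0(substr(seq, 1, pos), strrep(m, k),
                    substr(seq, pos + 1, nchar(seq)))
    }
    if (i %% 7 == 0) {
      ch <- strsplit(seq, "")[[1]]
      ch[sample(length(ch), 3)] <- "N"
      seq <- paste(ch, collapse = "")
    }
    for (minrep in c(2, 5)) {
      got <- find_ssrs(make_records(x = seq), detection_config(2, 6, minrep))
      want <- oracle_find_ssrs(seq, 2, 6, minrep)
      expect_equal(nrow(got), nrow(want))
      if (nrow(got) > 0) {
        expect_equal(got$motif, want$motif)
        expect_equal(got$start, want$start)
        expect_equal(got$end, want$end)
        expect_equal(got$repeat_count, want$repeat_count)
      }
    }
  }
})

test_that("reported loci verify perfection, maximality and uniqueness", {
  set.seed(202)
  for (i in 1:40) {
    seq <- paste0(random_dna(60), strrep("CA", sample(5:12, 1)),
                  random_dna(60), strrep("TTC", sample(5:8, 1)),
                  random_dna(60))
    loci <- find_ssrs(make_records(x = seq))
    expect_gte(nrow(loci), 2)
    expect_false(any(duplicated(loci[, c("start", "end")])))
    for (k in seq_len(nrow(loci))) {
      l <- loci[k, ]
      span <- substr(seq, l$start, l$end)
      expect_identical(span, strrep(l$motif, l$repeat_count))
      # extending by one period in either direction breaks the repeat
      if (l$start - l$period >= 1) {
        expect_false(substr(seq, l$start - l$period, l$start - 1) == l$motif)
      }
      after <- substr(seq, l$end + 1, l$end + l$period)
      if (nchar(after) == l$period) expect_false(after == l$motif)
    }
  }
})

test_that("detection is strand-asymmetric but maps to complement motifs on the other strand", {
  set.seed(303)
  seq <- plant_ssr(random_dna(80), "AG", 7, 41)
  L <- nchar(seq)
  fwd <- find_ssrs(make_records(x = seq))
  bwd <- find_ssrs(make_records(x = revcomp(seq)))
  expect_equal(nrow(fwd), nrow(bwd))
  f <- fwd[fwd$motif == "AG" & fwd$repeat_count == 7, ]
  b <- bwd[bwd$motif == "CT" & bwd$repeat_count == 7, ]
  expect_equal(nrow(f), 1L)
  expect_equal(nrow(b), 1L)
  expect_equal(b$start, L - f$end + 1L)
  expect_equal(b$end, L - f$start + 1L)
})
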