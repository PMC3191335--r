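test_that("GC percentage with error contracts", {
  expect_equal(gc_percent("ATGC"), 50.0)
  expect_equal(gc_percent("GGCC"), 100.0)
  expect_equal(gc_percent("AGTTCCGCCACATCCATTC"), 52.6)
  expect_error(gc_percent(""), "empty")
  expect_error(gc_percent("ACGNT"), "only A/C/G/T")
})

test_that("melting temperatures match frozen independent values per model", {
  # Wallace rule closed form: 2(A+T) + 4(G+C)
  twenty <- paste0(strrep("AT", 5), strrep("GC", 5))
  expect_equal(as.numeric(melt_tm(twenty, method = "wallace")), 60)
  # PRIMER3-classic (Breslauer 1986 + Schildkraut-Lifson): values frozen from
  # an independent implementation of the published tables
  expect_equal(as.numeric(melt_tm("AGTTCCGCCACATCCATTC")), 60.88, tolerance = 0.01)
  expect_equal(as.numeric(melt_tm("TAAGGGAAGGGGCGGAAC")), 62.25, tolerance = 0.01)
  # SantaLucia 1998 unified parameters, 50 mM Na+, 50 nM oligo
  expect_equal(as.numeric(melt_tm("AGTTCCGCCACATCCATTC", method = "santalucia")),
               52.06, tolerance = 0.01)
  expect_error(melt_tm("ACGTACG"), "at least 8")
  expect_error(melt_tm("ACGTACGN"), "only A/C/G/T")
})

test_that("Tm is invariant under reverse complement (duplex symmetry)", {
  set.seed(13)
  for (i in 1:20) {
    s <- random_dna(sample(18:27, 1))
    for (m in c("breslauer", "santalucia", "wallace")) {
      expect_equal(as.numeric(melt_tm(s, method = m)),
                   as.numeric(melt_tm(revcomp(s), method = m)),
                   tolerance = 1e-10)
    }
  }
})

test_that("complementarity scores match the exhaustive DP oracle", {
  expect_equal(complementarity_scores("AAAA", "TTTT")$any_comp, 4L)
  expect_gte(complementarity_scores("ACGT", "ACGT")$any_comp, 2L)
  expect_lte(complementarity_scores("AAAA", "GAGA")$any_comp, 1L)
  set.seed(17)
  for (i in 1:40) {
    a <- random_dna(sample(8:25, 1))
    b <- random_dna(sample(8:25, 1))
    got <- complementarity_scores(a, b)
    expect_equal(got$any_comp, oracle_lcs(a, oracle_revcomp(b)))
    expect_lte(got$three_prime_comp, got$any_comp)
    self <- complementarity_scores(a, a)
    expect_equal(self$any_comp, oracle_lcs(a, oracle_revcomp(a)))
  }
})

test_that("short flanks yield no candidates with the stated reason", {
  seq <- paste0("GCTAG", strrep("CA", 15), "TCGAT")
  recs <- make_records(x = seq)
  loci <- find_ssrs(recs)
  cands <- design_primers(recs, loci)
  expect_equal(nrow(cands), 0L)
  skipped <- attr(cands, "skipped")
  expect_equal(skipped$reason, "insufficient flank")
})

test_that("a well-flanked synthetic locus yields valid, ordered candidates", {
  set.seed(23)
  seq <- plant_ssr(random_dna(300), "CA", 15, 151)
  recs <- make_records(x = seq)
  loci <- find_ssrs(recs)
  loci <- loci[loci$motif == "CA" & loci$repeat_count == 15, ]
  expect_equal(nrow(loci), 1L)
  cons <- primer_constraints()
  cands <- design_primers(recs, loci, cons, max_candidates = 5)
  expect_gte(nrow(cands), 1L)
  expect_false(is.unsorted(cands$penalty))
  validate_candidates(cands, recs, find_ssrs(recs), cons)
  # determinism
  again <- design_primers(recs, loci, cons, max_candidates = 5)
  expect_equal(again, cands, ignore_attr = TRUE)
})

test_that("product size is coordinate arithmetic", {
  set.seed(29)
  seq <- paste0(random_dna(60), strrep("AG", 10), random_dna(60))
  recs <- make_records(x = seq)
  loci <- find_ssrs(recs)[1, ]
  cands <- design_primers(recs, loci,
                          primer_constraints(product_min = 80,
                                             product_max = 140,
                                             tm_min = 50, tm_max = 65))
  expect_gte(nrow(cands), 1L)
  expect_equal(cands$product_size, cands$rv_end - cands$fw_start + 1L)
})

test_that("tightening any single constraint never increases candidate count", {
  set.seed(37)
  seq <- paste0(random_dna(150), strrep("TC", 12), random_dna(150))
  recs <- make_records(x = seq)
  loci <- find_ssrs(recs)
  loci <- loci[loci$repeat_count == 12, ]
  base <- primer_constraints(tm_min = 52, tm_max = 63)
  n0 <- nrow(design_primers(recs, loci, base, max_candidates = 50))
  tighter <- list(
    primer_constraints(tm_min = 55, tm_max = 63),
    primer_constraints(tm_min = 52, tm_max = 60),
    primer_constraints(tm_min = 52, tm_max = 63, len_min = 20, len_max = 25),
    primer_constraints(tm_min = 52, tm_max = 63, gc_min = 40, gc_max = 60),
    primer_constraints(tm_min = 52, tm_max = 63, product_min = 150,
                       product_max = 250),
    primer_constraints(tm_min = 52, tm_max = 63, max_self_comp = 5,
                       max_3prime_comp = 3)
  )
  for (cons in tighter) {
    expect_lte(nrow(design_primers(recs, loci, cons, max_candidates = 50)), n0)
  }
})

test_that("primers never overlap any detected SSR of the template", {
  set.seed(41)
  # two SSRs; the second sits in the 3' flank of the first
  seq <- paste0(random_dna(120), strrep("CA", 10), random_dna(40),
                strrep("TTC", 7), random_dna(120))
  recs <- make_records(x = seq)
  loci <- find_ssrs(recs)
  expect_gte(nrow(loci), 2L)
  cons <- primer_constraints(tm_min = 52, tm_max = 63)
  cands <- design_primers(recs, loci, cons, max_candidates = 10)
  if (nrow(cands) > 0) validate_candidates(cands, recs, loci, cons)
})

test_that("marker sheet keeps the best pair per locus in Table-2-like columns", {
  set.seed(43)
  seq <- paste0(random_dna(150), strrep("GA", 11), random_dna(150))
  recs <- make_records(x = seq)
  loci <- find_ssrs(recs)
  cands <- design_primers(recs, loci, max_candidates = 5)
  sheet <- marker_sheet(cands)
  expect_equal(nrow(sheet), 1L)
  expect_named(sheet, c("name", "seq_id", "ssr", "product_size", "fw_primer",
                        "fw_tm", "rv_primer", "rv_tm"))
  expect_equal(sheet$ssr, "(GA)11")
  expect_equal(sheet$fw_primer, cands$fw_seq[which.min(cands$penalty)])
})
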