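test_that("plant_ssr inserts a maximal repeat and enforces flank rule", {
  bg <- strrep("G", 40)
  out <- plant_ssr(bg, "AT", 5, 20)
  expect_equal(stringr::str_count(out, "ATATATATAT"), 1L)
  expect_equal(nchar(out), 50L)
  # neighbours rewritten when they would extend the run in phase
  bg2 <- paste0(strrep("G", 20), "AC", strrep("G", 20))
  out2 <- plant_ssr(bg2, "AC", 5, 23)  # insertion right after an existing AC
  loci <- find_ssrs(make_records(x = out2), detection_config(2, 6, 5))
  hit <- loci[loci$motif == "AC", ]
  expect_equal(hit$repeat_count, 5L)
  expect_error(plant_ssr(bg, "AT", 5, 1), "at least one background base")
  expect_error(plant_ssr(bg, "ATAT", 3, 10), "not primitive")
})

test_that("simulation is deterministic and honours the null model", {
  p <- sim_params(n_sequences = 40, ssr_rate = 0, dup_rate = 0,
                  containment_rate = 0, flankless_rate = 0, tail_rate = 0,
                  seed = 7)
  a <- simulate_est_set(p)
  b <- simulate_est_set(p)
  expect_identical(a$records, b$records)
  expect_false(any(a$truth$loci$planted))
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(a$records, f1)
  write_fasta(b$records, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("sim_params validates its stated world", {
  expect_error(sim_params(n_sequences = 10), "seed")
  expect_error(sim_params(10, base_probs = c(A = .5, C = .5, G = 0, T = .1),
                          seed = 1), "sum to 1")
  expect_error(sim_params(10, dup_rate = 0.5, containment_rate = 0.4,
                          tail_rate = 0.3, seed = 1), "not exceed 1")
})

test_that("planted loci are recovered exactly by the detector", {
  p <- sim_params(n_sequences = 150, ssr_rate = 0.3, dup_rate = 0,
                  containment_rate = 0, flankless_rate = 0, tail_rate = 0,
                  seed = 11)
  sim <- simulate_est_set(p)
  planted <- sim$truth$loci[sim$truth$loci$planted, ]
  expect_gt(nrow(planted), 20)
  det <- find_ssrs(sim$records)
  key <- function(d, s, m, c) paste(d, s, m, c)
  expect_true(all(
    key(planted$seq_id, planted$start, planted$motif, planted$repeat_count)
    %in% key(det$seq_id, det$start, det$motif, det$repeat_count)
  ))
  # and the full detector output is exactly the truth (planted + incidental)
  tl <- sim$truth$loci
  expect_setequal(
    key(tl$seq_id, tl$start, tl$motif, tl$repeat_count),
    key(det$seq_id, det$start, det$motif, det$repeat_count)
  )
})

test_that("corruptions are emitted at the configured rates with exact truth", {
  p <- sim_params(n_sequences = 100, ssr_rate = 0.1, dup_rate = 0.05,
                  containment_rate = 0.05, flankless_rate = 0.04,
                  tail_rate = 0.2, seed = 23)
  sim <- simulate_est_set(p)
  tr <- sim$truth
  expect_equal(nrow(sim$records), 100 + 5 + 5 + 4)
  expect_equal(sum(tr$duplicate_pairs$relation == "identical"), 5L)
  expect_equal(sum(tr$duplicate_pairs$relation == "contained"), 5L)
  expect_equal(length(tr$flankless_ids), 4L)
  expect_equal(nrow(tr$tailed), 20L)
  seqs <- setNames(sim$records$sequence, sim$records$seq_id)
  for (k in seq_len(nrow(tr$duplicate_pairs))) {
    pr <- tr$duplicate_pairs[k, ]
    if (pr$relation == "identical") {
      expect_identical(seqs[[pr$copy]], seqs[[pr$original]])
    } else {
      expect_lt(nchar(seqs[[pr$copy]]), nchar(seqs[[pr$original]]))
      expect_true(startsWith(seqs[[pr$original]], seqs[[pr$copy]]))
    }
  }
  for (id in tr$flankless_ids) {
    loci <- find_ssrs(make_records(x = seqs[[id]]))
    expect_equal(loci$span_length, nchar(seqs[[id]]))
  }
  # tails are exactly removable: trimming restores the untailed core
  trimmed <- trim_poly_tails(sim$records)
  tcore <- setNames(trimmed$sequence, trimmed$seq_id)
  for (k in seq_len(nrow(tr$tailed))) {
    tl <- tr$tailed[k, ]
    expect_equal(nchar(tcore[[tl$seq_id]]),
                 nchar(seqs[[tl$seq_id]]) - tl$tail_len)
  }
})

test_that("generated composition tracks base_probs within 3 standard errors", {
  p <- sim_params(n_sequences = 400, ssr_rate = 0, dup_rate = 0,
                  containment_rate = 0, flankless_rate = 0, tail_rate = 0,
                  seed = 31)
  sim <- simulate_est_set(p)
  cs <- composition_stats(sim$records)
  n <- cs$total_bases
  expect_gt(n, 1e5)
  se <- 100 * sqrt(0.56 * 0.44 / n)
  expect_lt(abs(cs$pct_AT - 56), 3 * se + 0.05)  # 0.05 = reporting precision
})
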