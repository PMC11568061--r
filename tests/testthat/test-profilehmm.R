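test_that("a one-state forced model scores log2(20) bits on its consensus", {
  hmm <- single_state_hmm()
  expect_equal(viterbi_score(hmm, "A"), log2(20), tolerance = 1e-12)
  expect_equal(forward_score(hmm, "A"), log2(20), tolerance = 1e-12)
  expect_equal(profile_consensus(hmm), "A")
  expect_error(viterbi_score(hmm, ""), "empty input")
})

test_that("Viterbi and forward match exhaustive path enumeration", {
  cases <- expand.grid(m = 1:3, len = 1:4, rep = 1:2)
  for (k in seq_len(nrow(cases))) {
    hmm <- random_hmm(cases$m[k], seed = 1000 + k)
    set.seed(2000 + k)
    s <- paste(sample(AA20, cases$len[k], replace = TRUE), collapse = "")
    oracle <- hmm_path_oracle(hmm, s)
    expect_equal(viterbi_score(hmm, s), oracle$viterbi, tolerance = 1e-9,
                 label = sprintf("viterbi m=%d len=%d", cases$m[k], cases$len[k]))
    expect_equal(forward_score(hmm, s), oracle$forward, tolerance = 1e-6,
                 label = sprintf("forward m=%d len=%d", cases$m[k], cases$len[k]))
  }
})

test_that("forward dominates Viterbi on random model/sequence pairs", {
  for (k in 1:100) {
    hmm <- random_hmm(1 + k %% 4, seed = 3000 + k)
    set.seed(4000 + k)
    s <- paste(sample(AA20, 1 + k %% 6, replace = TRUE), collapse = "")
    expect_gte(forward_score(hmm, s) + 1e-12, viterbi_score(hmm, s))
  }
})

test_that("consensus scores at least as high as a one-off substitute", {
  hmm <- toy_hmm(list(one_hot("M", 0.1), one_hot("G", 0.1), one_hot("H", 0.1)))
  expect_gte(viterbi_score(hmm, "MGH"), viterbi_score(hmm, "MGA"))
})

test_that("build_from_msa applies Laplace smoothing and the gap cutoff", {
  m1 <- build_from_msa(msa(c("r1", "r2"), c("A", "A")), pseudocount = 1)
  expect_equal(m1$length, 1L)
  expect_equal(unname(m1$match_emissions[1, "A"]), 3 / 22)

  al <- msa(c("r1", "r2", "r3", "r4"),
            c("MG-KLV", "MG-KLV", "M--KIV", "MGAK-V"))
  mod <- build_from_msa(al, gap_fraction_cutoff = 0.5)
  # columns 1,2,4,6 have gap fraction < 0.5; column 3 (3/4 gaps) and
  # column 5 (1/4 gaps) -> 5 is kept too: majority-residue columns = 5
  expect_equal(mod$length, 5L)
  expect_error(build_from_msa(msa(c("a", "b"), c("-", "-"))), "degenerate")
  validate_profile_hmm(mod)
})

test_that("built and random models satisfy normalization invariants", {
  fam <- generate_family(ref_record, ref_anchor, 6L, 0.05, seed = 2)
  mod <- build_from_msa(msa(fam$id, fam$sequence))
  expect_silent(validate_profile_hmm(mod))
  expect_equal(mod$length, 398L)
  for (k in 1:5) expect_silent(validate_profile_hmm(random_hmm(3, seed = k)))
})

test_that("hmm_screen thresholds, preserves order, and is batch-invariant", {
  hmm <- toy_hmm(list(one_hot("M", 0.1), one_hot("G", 0.1)))
  recs <- records_df(c("x", "y", "z"), c("MG", "MGAA", "WW"))
  hits <- hmm_screen(hmm, recs, threshold = -Inf)
  expect_equal(hits$id, recs$id)
  expect_true(all(hits$passed))
  none <- hmm_screen(hmm, recs, threshold = max(hits$bit_score) + 1)
  expect_false(any(none$passed))
  # scores do not depend on batch composition
  solo <- hmm_screen(hmm, recs[2, ], threshold = 0)
  expect_equal(solo$bit_score, hits$bit_score[2])
  expect_equal(nrow(hmm_screen(hmm, recs[0, ])), 0L)
})

test_that("true family members all pass a threshold below their minimum score", {
  fam <- generate_family(ref_record, ref_anchor, 6L, 0.03, seed = 21)
  mod <- build_from_msa(msa(fam$id, fam$sequence))
  set <- generate_screen_set(synth_config(n_background = 5L, seed = 22))
  hits <- hmm_screen(mod, set$records, threshold = 150)
  truth <- set$truth$truth_label[match(hits$id, set$truth$id)]
  min_true <- min(hits$bit_score[truth == "true_mgl"])
  hits2 <- hmm_screen(mod, set$records, threshold = min_true - 1)
  expect_true(all(hits2$passed[truth == "true_mgl"]))
  # the default 150-bit cut separates family members from background here
  expect_true(all(hits$passed[truth == "true_mgl"]))
  expect_false(any(hits$passed[truth == "background"]))
})
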