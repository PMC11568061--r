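test_that("the synthetic reference carries the screen's study conditions", {
  expect_equal(nchar(ref_record$sequence), 398L)
  expect_equal(find_motifs(ref_record$sequence, "YGC"), 114L)
  expect_equal(find_motifs(ref_record$sequence, "KD"), 240L)
  expect_lt(abs(protein_mass(ref_record$sequence) - 43000), 150)
})

test_that("family generation is deterministic and anchor-protecting", {
  a <- generate_family(ref_record, ref_anchor, 5L, 0.1, seed = 42)
  b <- generate_family(ref_record, ref_anchor, 5L, 0.1, seed = 42)
  expect_identical(a, b)
  zero <- generate_family(ref_record, ref_anchor, 3L, 0, seed = 1)
  expect_true(all(zero$sequence == ref_record$sequence))
  for (s in a$sequence) {
    expect_equal(substr(s, 114, 116), "YGC")
    expect_equal(substr(s, 240, 241), "KD")
  }
})

test_that("family mutants hit the binomial Hamming expectation", {
  n <- 100L
  rate <- 0.1
  fam <- generate_family(ref_record, ref_anchor, n, rate, seed = 99)
  ref_chars <- strsplit(ref_record$sequence, "")[[1]]
  d <- vapply(fam$sequence, function(s)
    sum(strsplit(s, "")[[1]] != ref_chars), numeric(1))
  free_sites <- 398 - 5                       # two anchors, 5 residues
  expected <- rate * free_sites
  se <- sqrt(free_sites * rate * (1 - rate) / n)
  expect_lt(abs(mean(d) - expected), 3 * se + 0.5)  # 0.5 covers motif scrubbing
})

test_that("decoy classes are motif-faithful by construction", {
  no_ygc <- generate_decoys(ref_record, ref_anchor, "no_ygc", 10L, 0.05, seed = 5)
  expect_true(all(vapply(no_ygc$sequence, function(s)
    length(find_motifs(s, "YGC")) == 0L, logical(1))))
  no_kd <- generate_decoys(ref_record, ref_anchor, "no_kd", 10L, 0.05, seed = 6)
  expect_true(all(vapply(no_kd$sequence, function(s)
    length(find_motifs(s, "KD")) == 0L, logical(1))))
  mis <- generate_decoys(ref_record, ref_anchor, "misplaced", 10L, 0.05, seed = 7)
  for (s in mis$sequence) {
    pos <- find_motifs(s, "YGC")
    expect_length(pos, 1L)
    expect_gte(abs(pos - 114L), 30L)
    expect_equal(substr(s, 240, 241), "KD")
  }
  expect_error(generate_decoys(ref_record, ref_anchor, "bogus", 1L, 0, seed = 1),
               "arg")
})

test_that("background residue frequencies match the sampling vector", {
  bg <- generate_decoys(ref_record, ref_anchor, "background", 1000L, 0, seed = 8)
  expect_true(all(nchar(bg$sequence) >= 300L & nchar(bg$sequence) <= 500L))
  expect_true(all(vapply(bg$sequence, function(s)
    length(find_motifs(s, "YGC")) == 0L, logical(1))))
  chars <- unlist(strsplit(bg$sequence, ""))
  freq <- table(factor(chars, levels = AA20)) / length(chars)
  se <- sqrt(0.05 * 0.95 / length(chars))
  expect_true(all(abs(freq - 0.05) < 3 * se + 5e-4))  # slack for YGC scrubbing
})

test_that("screen sets conserve class counts and honour lineage weights", {
  cfg <- synth_config(seed = 11)
  set <- generate_screen_set(cfg)
  expect_equal(nrow(set$records), 25L)
  expect_equal(nrow(set$truth), 25L)
  expect_equal(unname(table(set$truth$truth_label)[
    c("true_mgl", "decoy_no_ygc", "decoy_no_kd", "decoy_misplaced",
      "background")]), rep(5L, 5), ignore_attr = TRUE)
  set2 <- generate_screen_set(cfg)
  expect_identical(set, set2)

  degenerate <- synth_config(seed = 3, phyla = data.frame(
    lineage = default_phyla()$lineage[1:2], weight = c(1, 0)))
  s3 <- generate_screen_set(degenerate)
  expect_true(all(s3$truth$lineage == default_phyla()$lineage[1]))
  expect_error(generate_screen_set(
    synth_config(0L, 0L, 0L, 0L, 0L, seed = 1)), "empty input")
})
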