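test_that("find_motifs reports all overlapping occurrences in order", {
  expect_equal(find_motifs("AYGCA", "YGC"), 2L)
  expect_equal(find_motifs("YGCYGC", "YGC"), c(1L, 4L))
  expect_equal(find_motifs("AAAA", "KD"), integer(0))
  expect_equal(find_motifs("AAAA", "AA"), 1:3)   # overlapping
  expect_error(find_motifs("AAAA", ""), "argument error")
})

test_that("the reference anchor validates its own motifs", {
  expect_silent(reference_anchor(ref_record))
  broken <- ref_record
  substr(broken$sequence, 116, 116) <- "H"
  expect_error(reference_anchor(broken), "anchor inconsistency")
})

test_that("the reference classifies as CONFIRMED at its own anchors", {
  v <- classify_candidate(ref_record, ref_anchor)
  expect_equal(v$status, "CONFIRMED")
  expect_equal(v$anchor_mapped_1, 114L)
  expect_equal(v$anchor_mapped_2, 240L)
})

test_that("each decoy class is rejected at its designed stage", {
  cys_to_his <- ref_record
  substr(cys_to_his$sequence, 116, 116) <- "H"
  expect_equal(classify_candidate(cys_to_his, ref_anchor)$status, "NO_YGC")

  for (seed in c(31, 32)) {
    mis <- generate_decoys(ref_record, ref_anchor, "misplaced", 3L, 0.03,
                           seed = seed)
    for (i in seq_len(3)) {
      v <- classify_candidate(mis[i, ], ref_anchor)
      expect_equal(v$status, "MISPLACED")
    }
    nk <- generate_decoys(ref_record, ref_anchor, "no_kd", 3L, 0.03,
                          seed = seed)
    expect_true(all(vapply(seq_len(3), function(i)
      classify_candidate(nk[i, ], ref_anchor)$status, "") == "NO_KD"))
  }
})

test_that("an insertion inside the anchored motif breaks contiguity", {
  s <- ref_record$sequence
  # split the anchored YGC with an inserted W; an intact distant copy keeps
  # the presence stage satisfied, so only the positional stage can reject
  split_motif <- paste0(substr(s, 1, 114), "W", substr(s, 115, 350), "YGC",
                        substr(s, 354, 398))
  cand <- list(id = "split", sequence = split_motif)
  v <- classify_candidate(cand, ref_anchor)
  expect_equal(v$status, "MISPLACED")
  # a tolerance window does not rescue it either: the distant copy is
  # far from the mapped anchor
  expect_equal(classify_candidate(cand, ref_anchor,
                                  position_tolerance = 2L)$status, "MISPLACED")
})

test_that("screen_batch reproduces the designed funnel and truth labels", {
  set <- generate_screen_set(synth_config(mutation_rate = 0, seed = 7))
  scr <- screen_batch(set$records, ref_anchor)
  expect_equal(unname(scr$funnel), c(25L, 25L, 15L, 10L, 5L))
  got <- scr$verdicts$status[match(set$truth$id, scr$verdicts$id)]
  expect_equal(got, expected_status(set$truth$truth_label))
  expect_true(all(diff(scr$funnel) <= 0))

  one <- screen_batch(records_df(ref_record$id, ref_record$sequence), ref_anchor)
  expect_equal(unname(one$funnel), rep(1L, 5))
  empty <- screen_batch(records_df(character(0), character(0)), ref_anchor)
  expect_equal(unname(empty$funnel), rep(0L, 5))
})

test_that("perfect truth recovery holds across seeds at low divergence", {
  for (seed in 1:10) {
    set <- generate_screen_set(synth_config(n_true = 3L, n_no_ygc = 3L,
                                            n_no_kd = 3L, n_misplaced = 3L,
                                            n_background = 3L,
                                            mutation_rate = 0.05, seed = seed))
    scr <- screen_batch(set$records, ref_anchor)
    got <- scr$verdicts$status[match(set$truth$id, scr$verdicts$id)]
    expect_equal(got, expected_status(set$truth$truth_label),
                 label = paste("seed", seed))
  }
})

test_that("HMM gating assigns NO_HMM_HIT and skips motif stages", {
  set <- generate_screen_set(synth_config(mutation_rate = 0, seed = 7))
  hits <- data.frame(id = set$records$id, bit_score = 0,
                     passed = set$records$truth_label != "background")
  scr <- screen_batch(set$records, ref_anchor, hmm_hits = hits)
  expect_equal(unname(scr$funnel), c(25L, 20L, 15L, 10L, 5L))
  st <- scr$verdicts$status[match(set$truth$id, scr$verdicts$id)]
  expect_equal(st, expected_status(set$truth$truth_label, hmm_stage = TRUE))
})

test_that("the annotation filter demotes disagreeing labels only", {
  set <- generate_screen_set(synth_config(mutation_rate = 0, seed = 7))
  scr <- screen_batch(set$records, ref_anchor)
  keep <- data.frame(id = scr$verdicts$id, label = "methionine-gamma-lyase")
  expect_equal(apply_annotation_filter(scr$verdicts, keep), scr$verdicts)
  empty <- data.frame(id = character(0), label = character(0))
  expect_equal(apply_annotation_filter(scr$verdicts, empty), scr$verdicts)
  one <- data.frame(id = scr$verdicts$id[1], label = "cystathionine gamma-lyase")
  demoted <- apply_annotation_filter(scr$verdicts, one)
  expect_equal(demoted$status[1], "REJECTED_ANNOTATION")
  expect_equal(demoted$status[-1], scr$verdicts$status[-1])
  expect_error(apply_annotation_filter(scr$verdicts, data.frame(id = "x")),
               "schema error")
})
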