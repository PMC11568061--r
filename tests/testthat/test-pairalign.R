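test_that("identity alignment gives 100% and the identity map", {
  al <- global_align("ACDE", "ACDE")
  expect_equal(al$identity_pct, 100)
  expect_equal(al$column_map, 1:4)
  expect_equal(al$aligned_a, "ACDE")
  for (i in 1:4) expect_equal(map_position(al, i), i)
})

test_that("affine gap costs follow open + (L - 1) * extend", {
  m <- matrix(-1, 24, 24,
              dimnames = list(c(AA20, "B", "X", "Z", "*"),
                              c(AA20, "B", "X", "Z", "*")))
  diag(m) <- 1
  al <- global_align("AA", "A", substitution_matrix = m,
                     gap_open = 2, gap_extend = 2)
  expect_equal(al$score, -1)           # one match, one opened gap
  # score symmetry under argument swap
  al2 <- global_align("A", "AA", substitution_matrix = m,
                      gap_open = 2, gap_extend = 2)
  expect_equal(al$score, al2$score)
  expect_error(global_align("", "A"), "empty input")
  expect_error(global_align("A1", "A"), "alphabet error")
})

test_that("global alignment matches the exhaustive all-alignments oracle", {
  blosum <- local({
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
    get("BLOSUM62", envir = e)
  })
  set.seed(77)
  for (k in 1:25) {
    a <- paste(sample(AA20[1:8], sample(2:6, 1), replace = TRUE), collapse = "")
    b <- paste(sample(AA20[1:8], sample(2:6, 1), replace = TRUE), collapse = "")
    got <- global_align(a, b, gap_open = 10, gap_extend = 3)
    want <- align_score_oracle(a, b, blosum, 10, 3)
    expect_equal(got$score, want, label = paste("align", a, b))
    # the reported alignment is consistent with its own score
    expect_equal(degap(got$aligned_a), a)
    expect_equal(degap(got$aligned_b), b)
  }
})

test_that("percent identity follows the chosen denominator to 2 decimals", {
  expect_equal(global_align("ACDE", "ACDF")$identity_pct, 75)
  al <- structure(list(aligned_a = "A-C", aligned_b = "AGC"),
                  class = "pair_alignment")
  expect_equal(percent_identity(al), 66.67)
  expect_equal(percent_identity(al, denominator = "shorter"), 100)
})

test_that("map_position walks alignment columns and flags gaps", {
  al <- structure(list(aligned_a = "A-CD", aligned_b = "ABCD",
                       column_map = NULL), class = "pair_alignment")
  al$column_map <- mglscreen:::compute_column_map(al$aligned_a, al$aligned_b)
  expect_equal(map_position(al, 2), 3L)     # a's C sits over b's C
  al2 <- structure(list(aligned_a = "ACD", aligned_b = "A-D",
                        column_map = NULL), class = "pair_alignment")
  al2$column_map <- mglscreen:::compute_column_map(al2$aligned_a, al2$aligned_b)
  expect_true(is.na(map_position(al2, 2)))
  expect_error(map_position(al2, 9), "bounds error")
})

test_that("reference-anchored star MSA merges on reference coordinates", {
  recs <- records_df(c("c1", "c2", "c3"),
                     c(ref_record$sequence, ref_record$sequence,
                       ref_record$sequence))
  al <- reference_anchored_msa(ref_record, recs)
  expect_equal(al$ncol, 398L)
  expect_true(all(al$seqs == ref_record$sequence))

  # an insertion in one record opens a shared gap column in all rows
  ins <- paste0(substr(ref_record$sequence, 1, 200), "WWW",
                substr(ref_record$sequence, 201, 398))
  al2 <- reference_anchored_msa(ref_record, records_df(c("plain", "ins"),
                                                       c(ref_record$sequence, ins)))
  expect_equal(al2$ncol, 401L)
  expect_equal(degap(al2)[1], ref_record$sequence)
  expect_equal(degap(al2)[2], ref_record$sequence)
  expect_equal(degap(al2)[3], ins)
  expect_error(reference_anchored_msa(ref_record, records_df(character(0),
                                                             character(0))),
               "empty input")
})
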