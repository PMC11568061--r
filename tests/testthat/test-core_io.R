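test_that("read_fasta normalizes headers, case, and terminal stops", {
  f <- write_tmp(c(">a desc here", "mghk", ">b", "MG*"), ".fasta")
  recs <- read_fasta(f)
  expect_equal(recs$id, c("a", "b"))
  expect_equal(recs$description, c("desc here", ""))
  expect_equal(recs$sequence, c("MGHK", "MG"))
})

test_that("read_fasta rejects duplicates, empties, and illegal characters", {
  expect_error(read_fasta(write_tmp(c(">a", "MG", ">a", "KK"), ".fasta")),
               "duplicate id.*'a'")
  expect_error(read_fasta(write_tmp("", ".fasta")), "empty input")
  expect_error(read_fasta(write_tmp(c(">a", "MG1K"), ".fasta")),
               "line 2.*illegal character")
  expect_error(read_fasta(write_tmp(c(">a", "MG*K"), ".fasta")),
               "internal stop")
  expect_warning(recs <- read_fasta(write_tmp(c(">a", "MBGZ"), ".fasta")),
                 "mapped to X")
  expect_equal(recs$sequence, "MXGX")
})

test_that("FASTA round-trips and honours wrap_width", {
  recs <- records_df(c("r1", "r2", "r3"),
                     c("MGHKLVVA", "ACDEFGHIKLMNPQRSTVWY", "MX"),
                     desc = c("one", "", "three"))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, f)
  expect_equal(read_fasta(f), recs)
  write_fasta(records_df("a", "MGHK"), f, wrap_width = 2L)
  expect_equal(readLines(f), c(">a", "MG", "HK"))
  write_fasta(recs[0, ], f)
  expect_equal(length(readLines(f)), 0L)
})

test_that("parsing is insensitive to CRLF line endings", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeBin(charToRaw(">a d\r\nMGHK\r\n>b\r\nAC\r\n"), f)
  recs <- read_fasta(f)
  expect_equal(recs$sequence, c("MGHK", "AC"))
  s <- withr::local_tempfile(fileext = ".sto")
  writeBin(charToRaw("# STOCKHOLM 1.0\r\nr1 AC-D\r\nr2 A.CD\r\n//\r\n"), s)
  al <- read_stockholm(s)
  expect_equal(al$seqs, c("AC-D", "A-CD"))
})

test_that("read_stockholm handles blocks, gap normalization, and shape errors", {
  f <- write_tmp(c("# STOCKHOLM 1.0", "#=GF ID toy", "r1 AC.D", "r2 ACCD",
                   "", "r1 EF", "r2 EF", "//"))
  al <- read_stockholm(f)
  expect_equal(al$ncol, 6L)
  expect_equal(al$seqs, c("AC-DEF", "ACCDEF"))
  expect_error(read_stockholm(write_tmp(c("r1 ACD", "r2 AC"))),
               "alignment-shape")
  expect_error(read_stockholm(write_tmp(c("# STOCKHOLM 1.0", "//"))),
               "empty input")
})

test_that("HMMER3 profiles round-trip through the ASCII format", {
  hmm <- toy_hmm(list(one_hot("A", eps = 0.05), one_hot("C", eps = 0.05)))
  f <- write_tmp(hmmer3_text(hmm), ".hmm")
  got <- read_hmmer3_profile(f)
  expect_equal(got$length, 2L)
  expect_equal(got$match_emissions, hmm$match_emissions, tolerance = 1e-4)
  expect_equal(got$transitions, hmm$transitions, tolerance = 1e-4)
  expect_equal(got$background, hmm$background, tolerance = 1e-4)
  # '*' encodes probability zero
  expect_equal(unname(got$match_emissions[1, "D"]) > 0, TRUE)
  expect_equal(unname(got$transitions[3, "MD"]), 0)
})

test_that("HMMER3 parser rejects bad magic and LENG mismatches", {
  hmm <- toy_hmm(list(one_hot("A", eps = 0.05)))
  txt <- hmmer3_text(hmm)
  expect_error(read_hmmer3_profile(write_tmp(sub("HMMER3/f", "HMMER2.0", txt))),
               "format error")
  expect_error(read_hmmer3_profile(write_tmp(sub("LENG  1", "LENG  2", txt))),
               "LENG mismatch")
})

test_that("tables enforce schema and round-trip", {
  f <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(id = c("a", "b"), lineage = c("x", "y"),
                    stringsAsFactors = FALSE)
  write_table(tab, f)
  expect_equal(read_table(f, c("id", "lineage")), tab)
  expect_error(read_table(f, c("id", "label")), "schema error.*'label'")
})
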