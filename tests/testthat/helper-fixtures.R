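# fixture builders shared across test files; everything is generated in
# code, nothing is read from disk except files the tests write themselves

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

records_df <- function(ids, seqs, desc = "") {
  data.frame(id = ids, description = rep_len(desc, length(ids)),
             sequence = seqs, stringsAsFactors = FALSE)
}

write_tmp <- function(lines, ext = ".txt") {
  f <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# a structurally valid profile HMM with given match emission rows
# (list of length-20 probability vectors) and optional transition rows
toy_hmm <- function(match_rows, transitions = NULL, bg = rep(1 / 20, 20)) {
  m <- length(match_rows)
  me <- do.call(rbind, match_rows)
  ie <- matrix(bg, m + 1, 20, byrow = TRUE)
  if (is.null(transitions)) {
    tr <- matrix(rep(c(0.8, 0.1, 0.1, 0.5, 0.5, 0.6, 0.4), each = m + 1),
                 m + 1, 7)
    colnames(tr) <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
    tr[1, c("DM", "DD")] <- c(1, 0)
    tr[m + 1, c("MM", "MI", "MD")] <- c(0.9, 0.1, 0)
    tr[m + 1, c("DM", "DD")] <- c(1, 0)
    transitions <- tr
  }
  profile_hmm(me, ie, transitions, bg)
}

# emission row concentrated on one residue
one_hot <- function(letter, eps = 0) {
  p <- rep(eps / 19, 20)
  names(p) <- AA20
  p[letter] <- 1 - eps
  p
}

# degenerate single-path model: begin -> M1 -> end with P(A) = 1
single_state_hmm <- function() {
  tr <- matrix(0, 2, 7, dimnames = list(NULL, c("MM", "MI", "MD",
                                                "IM", "II", "DM", "DD")))
  tr[, "MM"] <- 1
  tr[, "IM"] <- 1
  tr[, "DM"] <- 1
  toy_hmm(list(one_hot("A")), transitions = tr)
}

# random valid profile HMM for property sweeps
random_hmm <- function(m, seed) {
  set.seed(seed)
  rdir <- function(k) { x <- rgamma(k, 1); x / sum(x) }
  me <- t(replicate(m, rdir(20)))
  ie <- t(replicate(m + 1, rdir(20)))
  tr <- matrix(0, m + 1, 7, dimnames = list(NULL, c("MM", "MI", "MD",
                                                    "IM", "II", "DM", "DD")))
  for (j in seq_len(m + 1)) {
    tr[j, c("MM", "MI", "MD")] <- rdir(3)
    tr[j, c("IM", "II")] <- rdir(2)
    tr[j, c("DM", "DD")] <- rdir(2)
  }
  tr[1, c("DM", "DD")] <- c(1, 0)
  tr[m + 1, c("MM", "MI")] <- tr[m + 1, c("MM", "MI")] / sum(tr[m + 1, c("MM", "MI")])
  tr[m + 1, "MD"] <- 0
  tr[m + 1, c("DM", "DD")] <- c(1, 0)
  profile_hmm(me, ie, tr, rdir(20))
}

# render a profile HMM as HMMER3/f ASCII text (round-trip fixture)
hmmer3_text <- function(hmm) {
  fmt <- function(p) ifelse(p == 0, "*", sprintf("%.5f", -log(p)))
  row <- function(v) paste(fmt(v), collapse = "  ")
  m <- hmm$length
  out <- c("HMMER3/f [toy]",
           "NAME  toy",
           paste("LENG ", m),
           "ALPH  amino",
           paste("HMM  ", paste(AA20, collapse = "  ")),
           "      m->m  m->i  m->d  i->m  i->i  d->m  d->d",
           paste("  COMPO  ", row(hmm$background)),
           paste("         ", row(hmm$insert_emissions[1, ])),
           paste("         ", row(hmm$transitions[1, ])))
  for (k in seq_len(m)) {
    out <- c(out,
             paste("     ", k, " ", row(hmm$match_emissions[k, ]), " 1 - - -"),
             paste("         ", row(hmm$insert_emissions[k + 1, ])),
             paste("         ", row(hmm$transitions[k + 1, ])))
  }
  c(out, "//")
}

# shared synthetic study objects (computed once per test run)
ref_record <- synthetic_reference()
ref_anchor <- reference_anchor(ref_record)
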