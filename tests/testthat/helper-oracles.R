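# Independent oracles used to cross-check the dynamic-programming
# implementations.  These enumerate exhaustively and share no code with
# the package internals.

# enumerate every state path of a profile HMM that emits `sequence`
# exactly; returns best-path and sum-over-paths bit scores vs the null
hmm_path_oracle <- function(hmm, sequence) {
  x <- strsplit(sequence, "")[[1]]
  n <- length(x)
  m <- hmm$length
  tr <- hmm$transitions
  me <- hmm$match_emissions
  ie <- hmm$insert_emissions
  probs <- numeric(0)

  rec <- function(state, node, i, p) {
    if (p == 0) return(invisible())
    row <- node + 1L
    if (state == "M") {
      if (node == m) {
        if (i == n) probs <<- c(probs, p * tr[row, "MM"])
      } else if (i < n) {
        rec("M", node + 1L, i + 1L, p * tr[row, "MM"] * me[node + 1L, x[i + 1L]])
      }
      if (i < n) rec("I", node, i + 1L, p * tr[row, "MI"] * ie[row, x[i + 1L]])
      if (node < m) rec("D", node + 1L, i, p * tr[row, "MD"])
    } else if (state == "I") {
      if (node == m) {
        if (i == n) probs <<- c(probs, p * tr[row, "IM"])
      } else if (i < n) {
        rec("M", node + 1L, i + 1L, p * tr[row, "IM"] * me[node + 1L, x[i + 1L]])
      }
      if (i < n) rec("I", node, i + 1L, p * tr[row, "II"] * ie[row, x[i + 1L]])
    } else {                             # D
      if (node == m) {
        if (i == n) probs <<- c(probs, p * tr[row, "DM"])
      } else if (i < n) {
        rec("M", node + 1L, i + 1L, p * tr[row, "DM"] * me[node + 1L, x[i + 1L]])
      }
      if (node < m) rec("D", node + 1L, i, p * tr[row, "DD"])
    }
    invisible()
  }
  rec("M", 0L, 0L, 1)
  null_p <- prod(hmm$background[x])
  list(viterbi = log2(max(probs, 0) / null_p),
       forward = log2(sum(probs) / null_p))
}

# exhaustive global-alignment oracle with affine gap runs costing
# gap_open + (L - 1) * gap_extend; enumerates every alignment
align_score_oracle <- function(a, b, mat, gap_open, gap_extend) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  best <- -Inf
  rec <- function(i, j, prev, sc) {
    if (i == na && j == nb) {
      best <<- max(best, sc)
      return(invisible())
    }
    if (i < na && j < nb)
      rec(i + 1L, j + 1L, "M", sc + mat[ca[i + 1L], cb[j + 1L]])
    if (i < na)
      rec(i + 1L, j, "U", sc - if (prev == "U") gap_extend else gap_open)
    if (j < nb)
      rec(i, j + 1L, "L", sc - if (prev == "L") gap_extend else gap_open)
    invisible()
  }
  rec(0L, 0L, "S", 0)
  best
}

# random rooted tree with branch lengths in [0.1, 2]; its cophenetic
# matrix is additive by construction
random_additive_case <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa, br = function(k) runif(k, 0.1, 2))
  list(tree = tr, d = cophenetic(tr))
}
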