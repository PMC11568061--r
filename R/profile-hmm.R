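TRANS_CLASSES <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")

#' Construct a profile hidden Markov model
#'
#' A plan7-style profile with `M` match states, `M + 1` insert states
#' (`I_0 ... I_M`) and `M` delete states, plus a background null model.
#' Transition row `j` (1-based row `j + 1`) holds the probabilities out of
#' node `j`'s states into node `j + 1`: `MM, MI, MD` out of `M_j` (node 0's
#' "match" state is the begin state), `IM, II` out of `I_j`, and `DM, DD`
#' out of `D_j`.  The last row's `MM`, `IM` and `DM` lead to the end state.
#'
#' @param match_emissions `M x 20` matrix of match emission probabilities
#'   (columns in alphabetical amino-acid order).
#' @param insert_emissions `(M + 1) x 20` matrix of insert emission
#'   probabilities for `I_0 ... I_M`.
#' @param transitions `(M + 1) x 7` matrix with columns
#'   `MM, MI, MD, IM, II, DM, DD`.
#' @param background Length-20 vector of null-model residue frequencies.
#' @param validate Check normalization invariants (default `TRUE`).
#' @return An object of class `profile_hmm`.
#' @export
profile_hmm <- function(match_emissions, insert_emissions, transitions,
                        background, validate = TRUE) {
  match_emissions <- as.matrix(match_emissions)
  insert_emissions <- as.matrix(insert_emissions)
  transitions <- as.matrix(transitions)
  m <- nrow(match_emissions)
  stopifnot(m >= 1L, ncol(match_emissions) == 20L,
            nrow(insert_emissions) == m + 1L, ncol(insert_emissions) == 20L,
            nrow(transitions) == m + 1L, ncol(transitions) == 7L,
            length(background) == 20L)
  colnames(match_emissions) <- colnames(insert_emissions) <- AA_LETTERS
  colnames(transitions) <- TRANS_CLASSES
  obj <- structure(list(length = m,
                        match_emissions = match_emissions,
                        insert_emissions = insert_emissions,
                        transitions = transitions,
                        background = setNames(as.numeric(background), AA_LETTERS)),
                   class = "profile_hmm")
  if (validate) validate_profile_hmm(obj)
  obj
}

#' Validate profile-HMM normalization invariants
#'
#' Every emission row and every state's outgoing transition distribution
#' must sum to 1 within `tol`.
#'
#' @param hmm A [profile_hmm()] object.
#' @param tol Absolute tolerance (default `1e-9`).
#' @return Invisibly, `hmm`; errors on violation.
#' @export
validate_profile_hmm <- function(hmm, tol = 1e-9) {
  stopifnot(inherits(hmm, "profile_hmm"))
  m <- hmm$length
  chk <- function(x, what) {
    bad <- which(abs(x - 1) > tol)
    if (length(bad))
      stop("profile invariant violated: ", what, " row(s) ",
           paste(bad, collapse = ", "), " do not sum to 1")
  }
  chk(rowSums(hmm$match_emissions), "match emission")
  chk(rowSums(hmm$insert_emissions), "insert emission")
  chk(abs(sum(hmm$background)), "background")
  tr <- hmm$transitions
  chk(rowSums(tr[, c("MM", "MI", "MD"), drop = FALSE]), "M-state transition")
  chk(rowSums(tr[, c("IM", "II"), drop = FALSE]), "I-state transition")
  chk(rowSums(tr[, c("DM", "DD"), drop = FALSE]), "D-state transition")
  if (tr[m + 1L, "MD"] > tol || tr[m + 1L, "DD"] > tol || tr[1L, "DD"] > tol)
    stop("profile invariant violated: structurally impossible transition has mass")
  invisible(hmm)
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("profile HMM with", x$length, "match states\n")
  invisible(x)
}

#' Build a profile HMM from a seed alignment
#'
#' Columns whose gap fraction is below `gap_fraction_cutoff` become match
#' states.  Match emissions are Laplace-smoothed observed frequencies,
#' `P(a) = (count_a + pseudocount) / (n_observed + 20 * pseudocount)`;
#' transitions are estimated from each row's match/insert/delete path with
#' the same smoothing; insert emissions equal the background, which is the
#' smoothed overall residue frequency of the alignment.  `X` residues are
#' skipped when counting emissions but traverse the state path normally.
#'
#' @param msa A [msa()] seed alignment.
#' @param gap_fraction_cutoff Columns with gap fraction strictly below this
#'   become match states (default 0.5).
#' @param pseudocount Laplace pseudocount (default 1).
#' @return A [profile_hmm()].
#' @export
build_from_msa <- function(msa, gap_fraction_cutoff = 0.5, pseudocount = 1) {
  stopifnot(inherits(msa, "protein_msa"), pseudocount > 0)
  chars <- do.call(rbind, strsplit(msa$seqs, ""))
  n_rows <- nrow(chars)
  gap_frac <- colMeans(chars == "-")
  match_cols <- which(gap_frac < gap_fraction_cutoff)
  m <- length(match_cols)
  if (m == 0L)
    stop("degenerate model: no column has gap fraction below ",
         gap_fraction_cutoff)

  pc <- pseudocount
  count_aa <- function(v) {
    v <- v[v %in% AA_LETTERS]
    tabulate(match(v, AA_LETTERS), nbins = 20L)
  }
  match_em <- t(vapply(match_cols, function(cl) {
    cnt <- count_aa(chars[, cl])
    (cnt + pc) / (sum(cnt) + 20 * pc)
  }, numeric(20)))

  bg_cnt <- count_aa(as.vector(chars))
  background <- (bg_cnt + pc) / (sum(bg_cnt) + 20 * pc)
  ins_em <- matrix(background, m + 1L, 20, byrow = TRUE)

  # per-row state paths: match column -> M (residue) or D (gap);
  # insert column residue -> I at the current node; begin/end count as M
  is_match <- seq_len(msa$ncol) %in% match_cols
  cnt <- array(0, dim = c(m + 1L, 3L, 3L),
               dimnames = list(NULL, c("M", "I", "D"), c("M", "I", "D")))
  for (r in seq_len(n_rows)) {
    state <- "M"; node <- 0L
    for (cl in seq_len(msa$ncol)) {
      if (is_match[cl]) {
        nxt <- if (chars[r, cl] == "-") "D" else "M"
        cnt[node + 1L, state, nxt] <- cnt[node + 1L, state, nxt] + 1
        state <- nxt; node <- node + 1L
      } else if (chars[r, cl] != "-") {
        cnt[node + 1L, state, "I"] <- cnt[node + 1L, state, "I"] + 1
        state <- "I"
      }
    }
    cnt[m + 1L, state, "M"] <- cnt[m + 1L, state, "M"] + 1   # -> end
  }

  trans <- matrix(0, m + 1L, 7, dimnames = list(NULL, TRANS_CLASSES))
  for (j in seq_len(m + 1L)) {
    last <- j == m + 1L
    mm <- cnt[j, "M", ]
    if (last) {
      trans[j, c("MM", "MI")] <- (mm[c("M", "I")] + pc) / (sum(mm[c("M", "I")]) + 2 * pc)
    } else {
      trans[j, c("MM", "MI", "MD")] <- (mm + pc) / (sum(mm) + 3 * pc)
    }
    ii <- cnt[j, "I", ]
    trans[j, c("IM", "II")] <- (ii[c("M", "I")] + pc) / (sum(ii[c("M", "I")]) + 2 * pc)
    dd <- cnt[j, "D", ]
    if (j == 1L || last) {
      trans[j, c("DM", "DD")] <- c(1, 0)   # D_0 / beyond-last-node do not exist
    } else {
      trans[j, c("DM", "DD")] <- (dd[c("M", "D")] + pc) / (sum(dd[c("M", "D")]) + 2 * pc)
    }
  }
  profile_hmm(match_em, ins_em, trans, background)
}

# per-position log2-odds emission scores; X scores 0 bits against the null
emission_bits <- function(em_row_log, bg_log, x) {
  ifelse(x == "X", 0, em_row_log[x] - bg_log[x])
}

score_engine <- function(hmm, sequence, mode = c("viterbi", "forward")) {
  mode <- match.arg(mode)
  stopifnot(inherits(hmm, "profile_hmm"), is.character(sequence),
            length(sequence) == 1L)
  if (!nzchar(sequence)) stop("empty input: sequence has no residues")
  x <- strsplit(sequence, "")[[1]]
  if (!all(x %in% c(AA_LETTERS, "X")))
    stop("illegal residue(s) in sequence: ",
         paste(sQuote(unique(setdiff(x, c(AA_LETTERS, "X")))), collapse = ", "))
  m <- hmm$length
  n <- length(x)
  lt <- log2(hmm$transitions)
  lme <- log2(hmm$match_emissions)
  lie <- log2(hmm$insert_emissions)
  lbg <- log2(hmm$background)

  # esc[j, i]: match-state log-odds bits for residue i at node j
  known <- x != "X"
  esc <- matrix(0, m, n)
  isc <- matrix(0, m + 1L, n)
  if (any(known)) {
    idx <- match(x[known], AA_LETTERS)
    esc[, known] <- lme[, idx, drop = FALSE] - rep(lbg[idx], each = m)
    isc[, known] <- lie[, idx, drop = FALSE] - rep(lbg[idx], each = m + 1L)
  }

  cmb2 <- if (mode == "viterbi") pmax else function(a, b) {
    mx <- pmax(a, b); r <- mx + log2(2^(a - mx) + 2^(b - mx))
    r[mx == -Inf] <- -Inf
    r
  }
  cmb3 <- function(a, b, c) cmb2(cmb2(a, b), c)

  jj <- seq_len(m)                       # node indices 1..M
  # unrolled delete chain: d[j+1] = max/lse over k <= j of
  # (m[k] + MD[k] + sum_{l=k+1..j} DD[l]); with cumulative DD sums the
  # Viterbi case reduces to a cummax (the -Inf at row 1 is excluded:
  # D_0 does not exist, so the chain can only start at node >= 1)
  cdd <- cumsum(c(0, lt[jj[-1L] , "DD"]))  # length m; cdd[j] = sum DD rows 2..j
  t_mm <- lt[jj, "MM"]; t_im <- lt[jj, "IM"]; t_dm <- lt[jj, "DM"]
  t_md <- lt[jj, "MD"]; t_mi <- lt[, "MI"]; t_ii <- lt[, "II"]
  d_chain <- function(mvec) {
    if (mode == "viterbi" && all(is.finite(cdd)))
      return(c(-Inf, cummax(mvec[jj] + t_md - cdd) + cdd))
    out <- rep(-Inf, m + 1L)
    for (j in jj)
      out[j + 1L] <- cmb2(mvec[j] + lt[j, "MD"], out[j] + lt[j, "DD"])
    out
  }
  vm <- c(0, rep(-Inf, m))               # position 0 (nothing emitted)
  vi <- rep(-Inf, m + 1L)
  vd <- d_chain(vm)                      # leading deletions
  for (i in seq_len(n)) {
    nm <- c(-Inf, esc[, i] + cmb3(vm[jj] + t_mm, vi[jj] + t_im,
                                  vd[jj] + t_dm))
    ni <- isc[, i] + cmb2(vm + t_mi, vi + t_ii)
    vd <- d_chain(nm)
    vm <- nm; vi <- ni
  }
  as.numeric(cmb3(vm[m + 1L] + lt[m + 1L, "MM"],
                  vi[m + 1L] + lt[m + 1L, "IM"],
                  vd[m + 1L] + lt[m + 1L, "DM"]))
}

#' Score a sequence against a profile HMM (best path)
#'
#' Global (whole-sequence, whole-model) Viterbi score in bits: the log2
#' odds of the best state path emitting the sequence versus the background
#' null model.  All dynamic programming is done in log space; `X` residues
#' contribute 0 bits against the null.
#'
#' @param hmm A [profile_hmm()].
#' @param sequence A protein sequence string.
#' @return The bit score (numeric scalar; may be `-Inf` if no path can emit
#'   the sequence).
#' @seealso [forward_score()] for the sum over all paths.
#' @export
viterbi_score <- function(hmm, sequence) score_engine(hmm, sequence, "viterbi")

#' Score a sequence against a profile HMM (all paths)
#'
#' Like [viterbi_score()] but summing over all state paths
#' (log-sum-exp); always greater than or equal to the Viterbi score.
#'
#' @inheritParams viterbi_score
#' @return The forward bit score.
#' @export
forward_score <- function(hmm, sequence) score_engine(hmm, sequence, "forward")

#' Consensus sequence of a profile HMM
#'
#' The highest-probability match residue at each node (ties broken
#' alphabetically).
#'
#' @param hmm A [profile_hmm()].
#' @return A sequence string of length `hmm$length`.
#' @export
profile_consensus <- function(hmm) {
  stopifnot(inherits(hmm, "profile_hmm"))
  paste(AA_LETTERS[apply(hmm$match_emissions, 1, which.max)], collapse = "")
}

#' Screen protein records against a profile HMM
#'
#' Scores every record with [viterbi_score()] and flags those at or above
#' the bit-score threshold.  The default threshold of 150 bits follows the
#' capture threshold used with the TIGR01328 methioninase model; because
#' this scorer uses a single-hit global alignment mode, the threshold
#' should be recalibrated for models built from other seeds (see the
#' vignette).
#'
#' @param hmm A [profile_hmm()].
#' @param records Data frame of protein records.
#' @param threshold Bit-score cutoff (finite, or `-Inf` to pass everything).
#' @return Data frame with columns `id`, `bit_score`, `passed`, in input
#'   order.
#' @export
hmm_screen <- function(hmm, records, threshold = 150) {
  stopifnot(inherits(hmm, "profile_hmm"), is.data.frame(records),
            is.numeric(threshold), length(threshold) == 1L, !is.na(threshold))
  if (nrow(records) == 0L)
    return(data.frame(id = character(0), bit_score = numeric(0),
                      passed = logical(0)))
  validate_records(records)
  scores <- vapply(records$sequence, function(s) viterbi_score(hmm, s),
                   numeric(1), USE.NAMES = FALSE)
  data.frame(id = records$id, bit_score = scores,
             passed = scores >= threshold, stringsAsFactors = FALSE)
}
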