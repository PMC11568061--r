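#' Read a HMMER3 ASCII profile
#'
#' Parses the `HMMER3/f` text format into the package's [profile_hmm()]
#' representation.  Emission and transition fields, stored as negative
#' natural-log probabilities (`*` meaning probability zero), are converted
#' to probabilities; the `COMPO` line supplies the background null
#' frequencies (uniform if absent).  Only the amino-acid alphabet is
#' supported.
#'
#' @param path Path to a HMMER3 ASCII profile file.
#' @return A [profile_hmm()] object of length `LENG`.
#' @export
read_hmmer3_profile <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("profile file not found: ", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  if (length(lines) == 0L) stop("empty input: '", path, "' has no content")
  if (!grepl("^HMMER3/f", lines[1]))
    stop("format error: expected 'HMMER3/f' magic, got ",
         sQuote(substr(lines[1], 1, 12)))

  leng <- NA_integer_
  hmm_at <- NA_integer_
  for (i in seq_along(lines)) {
    if (grepl("^LENG\\s", lines[i]))
      leng <- as.integer(sub("^LENG\\s+", "", lines[i]))
    if (grepl("^ALPH\\s", lines[i]) &&
        tolower(trimws(sub("^ALPH\\s+", "", lines[i]))) != "amino")
      stop("format error: only the amino alphabet is supported")
    if (grepl("^HMM\\s", lines[i])) { hmm_at <- i; break }
  }
  if (is.na(leng) || leng < 1L) stop("parse error: missing or invalid LENG")
  if (is.na(hmm_at)) stop("parse error: no HMM section found")

  to_p <- function(fields) {
    p <- ifelse(fields == "*", 0, exp(-suppressWarnings(as.numeric(fields))))
    if (anyNA(p)) stop("parse error: non-numeric emission/transition field")
    p
  }
  fields_of <- function(ln) strsplit(trimws(ln), "\\s+")[[1]]

  i <- hmm_at + 2L                     # skip the two header rows
  background <- rep(1 / 20, 20)
  if (grepl("^\\s*COMPO\\s", lines[i])) {
    background <- to_p(fields_of(lines[i])[2:21])
    background <- background / sum(background)
    i <- i + 1L
  }
  ins0 <- to_p(fields_of(lines[i])[1:20]); i <- i + 1L
  tr0 <- to_p(fields_of(lines[i])[1:7]);  i <- i + 1L

  match_em <- matrix(NA_real_, leng, 20)
  ins_em <- matrix(NA_real_, leng + 1L, 20)
  trans <- matrix(NA_real_, leng + 1L, 7)
  ins_em[1L, ] <- ins0
  trans[1L, ] <- tr0
  node <- 0L
  while (i <= length(lines) && !grepl("^//", lines[i])) {
    f <- fields_of(lines[i])
    k <- suppressWarnings(as.integer(f[1]))
    if (is.na(k) || k != node + 1L)
      stop("parse error: expected node ", node + 1L, ", got ", sQuote(f[1]))
    node <- k
    if (node > leng)
      stop("parse error: LENG mismatch: more nodes than LENG = ", leng)
    match_em[node, ] <- to_p(f[2:21])
    ins_em[node + 1L, ] <- to_p(fields_of(lines[i + 1L])[1:20])
    trans[node + 1L, ] <- to_p(fields_of(lines[i + 2L])[1:7])
    i <- i + 3L
  }
  if (node != leng)
    stop("parse error: LENG mismatch: found ", node, " nodes, LENG = ", leng)

  norm <- function(m) m / rowSums(m)
  colnames(match_em) <- colnames(ins_em) <- AA_LETTERS
  colnames(trans) <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
  # stored precision is ~5 decimals; renormalize before validating
  trans[1L, c("DM", "DD")] <- c(1, 0)
  trans[leng + 1L, c("MD", "DD")] <- 0
  mm <- trans[, c("MM", "MI", "MD")]; trans[, c("MM", "MI", "MD")] <- norm(mm)
  ii <- trans[, c("IM", "II")];       trans[, c("IM", "II")] <- norm(ii)
  dd <- trans[, c("DM", "DD")];       trans[, c("DM", "DD")] <- norm(dd)
  profile_hmm(match_emissions = norm(match_em),
              insert_emissions = norm(ins_em),
              transitions = trans,
              background = background / sum(background))
}
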