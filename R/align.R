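.matrix_cache <- new.env(parent = emptyenv())

resolve_matrix <- function(substitution_matrix) {
  if (is.matrix(substitution_matrix)) return(substitution_matrix)
  stopifnot(is.character(substitution_matrix), length(substitution_matrix) == 1L)
  if (!exists(substitution_matrix, envir = .matrix_cache)) {
    e <- new.env()
    utils::data(list = substitution_matrix, package = "Biostrings", envir = e)
    assign(substitution_matrix, get(substitution_matrix, envir = e),
           envir = .matrix_cache)
  }
  get(substitution_matrix, envir = .matrix_cache)
}

#' Global pairwise protein alignment with affine gaps
#'
#' Optimal Needleman-Wunsch alignment with Gotoh affine gap costs: a gap
#' run of length `L` costs `gap_open + (L - 1) * gap_extend`.  Defaults
#' echo the alignment parameters used for the original methioninase
#' screen (BLOSUM62, gap open 10, gap extend 3).
#'
#' @param a,b Protein sequence strings (non-empty).
#' @param substitution_matrix A scoring matrix or the name of one shipped
#'   with Biostrings (default `"BLOSUM62"`).
#' @param gap_open Cost of the first residue of a gap run (must be
#'   `>= gap_extend`).
#' @param gap_extend Cost of each subsequent gap residue.
#' @return An object of class `pair_alignment`: a list with `aligned_a`,
#'   `aligned_b` (equal-length gapped strings), `score`, `identity_pct`
#'   and `column_map` (for each 1-based position of `a`, the matched
#'   1-based position of `b`, or `NA` for a gap).
#' @examples
#' al <- global_align("AYGCA", "AYGA")
#' al$identity_pct
#' @export
global_align <- function(a, b, substitution_matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 3) {
  stopifnot(is.character(a), is.character(b),
            length(a) == 1L, length(b) == 1L)
  if (!nzchar(a) || !nzchar(b)) stop("empty input: sequences must be non-empty")
  if (gap_extend > gap_open)
    stop("gap_extend must not exceed gap_open")
  mat <- resolve_matrix(substitution_matrix)
  letters_ab <- unique(strsplit(paste0(a, b), "")[[1]])
  missing <- setdiff(letters_ab, rownames(mat))
  if (length(missing))
    stop("alphabet error: residue(s) ",
         paste(sQuote(missing), collapse = ", "),
         " absent from the substitution matrix")
  # Biostrings charges gapOpening + L * gapExtension for a length-L gap
  pa <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "global",
    substitutionMatrix = mat,
    gapOpening = gap_open - gap_extend, gapExtension = gap_extend)
  aligned_a <- as.character(Biostrings::alignedPattern(pa))
  aligned_b <- as.character(Biostrings::alignedSubject(pa))
  res <- structure(list(a = a, b = b,
                        aligned_a = unname(aligned_a),
                        aligned_b = unname(aligned_b),
                        score = Biostrings::score(pa),
                        identity_pct = NA_real_,
                        column_map = NULL),
                   class = "pair_alignment")
  res$column_map <- compute_column_map(res$aligned_a, res$aligned_b)
  res$identity_pct <- percent_identity(res)
  res
}

compute_column_map <- function(aligned_a, aligned_b) {
  ca <- strsplit(aligned_a, "")[[1]]
  cb <- strsplit(aligned_b, "")[[1]]
  pos_b <- cumsum(cb != "-")
  map <- ifelse(cb[ca != "-"] == "-", NA_integer_, pos_b[ca != "-"])
  as.integer(map)
}

#' @export
print.pair_alignment <- function(x, ...) {
  cat("global alignment:", nchar(x$aligned_a), "columns, score",
      format(x$score), ", identity", sprintf("%.2f%%", x$identity_pct), "\n")
  invisible(x)
}

#' Percent identity of a pairwise alignment
#'
#' `100 * identical-residue columns / denominator`, reported to two
#' decimals.  The default denominator is the total number of alignment
#' columns (BLAST-style); `"shorter"` divides by the length of the shorter
#' ungapped sequence instead.
#'
#' @param result A `pair_alignment` from [global_align()].
#' @param denominator `"alignment"` (default) or `"shorter"`.
#' @return Percentage in `[0, 100]`.
#' @export
percent_identity <- function(result, denominator = c("alignment", "shorter")) {
  stopifnot(inherits(result, "pair_alignment"))
  denominator <- match.arg(denominator)
  ca <- strsplit(result$aligned_a, "")[[1]]
  cb <- strsplit(result$aligned_b, "")[[1]]
  ident <- sum(ca == cb & ca != "-")
  den <- switch(denominator,
                alignment = length(ca),
                shorter = min(sum(ca != "-"), sum(cb != "-")))
  round(100 * ident / den, 2)
}

#' Map a sequence position through an alignment
#'
#' Transfers a 1-based position in sequence `a` to the matched 1-based
#' position in sequence `b`, or `NA` if `b` has a gap in that column.
#'
#' @param result A `pair_alignment` from [global_align()].
#' @param pos_in_a 1-based position in the ungapped `a` sequence.
#' @return Integer position in `b`, or `NA_integer_` for a gap.
#' @export
map_position <- function(result, pos_in_a) {
  stopifnot(inherits(result, "pair_alignment"),
            is.numeric(pos_in_a), length(pos_in_a) == 1L)
  n <- length(result$column_map)
  if (is.na(pos_in_a) || pos_in_a < 1 || pos_in_a > n)
    stop("bounds error: position ", pos_in_a, " outside 1..", n)
  result$column_map[[as.integer(pos_in_a)]]
}

#' Reference-anchored star multiple alignment
#'
#' Aligns every record pairwise to the reference and merges the pairwise
#' alignments on reference coordinates ("once a gap, always a gap"):
#' insertions relative to the reference open a shared gap column block in
#' all other rows.  The reference row comes first.  This provides exactly
#' the candidate-to-reference coordinate transfer the positional motif
#' validation needs; it is not a general progressive MSA.
#'
#' @param reference A single protein record (list or one-row data frame
#'   with `id` and `sequence`).
#' @param records Data frame of protein records (non-empty).
#' @param substitution_matrix,gap_open,gap_extend Passed to
#'   [global_align()].
#' @return A [msa()] object with `nrow(records) + 1` rows.
#' @export
reference_anchored_msa <- function(reference, records,
                                   substitution_matrix = "BLOSUM62",
                                   gap_open = 10, gap_extend = 3) {
  ref <- as_record(reference)
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) stop("empty input: no records to align")
  validate_records(records)
  L <- nchar(ref$sequence)
  ref_chars <- strsplit(ref$sequence, "")[[1]]

  parts <- lapply(records$sequence, function(s) {
    al <- global_align(ref$sequence, s, substitution_matrix = substitution_matrix,
                       gap_open = gap_open, gap_extend = gap_extend)
    ca <- strsplit(al$aligned_a, "")[[1]]
    cb <- strsplit(al$aligned_b, "")[[1]]
    slot <- cumsum(ca != "-")            # 0 before first ref residue
    ins <- lapply(0:L, function(s0) cb[ca == "-" & slot == s0])
    matched <- cb[ca != "-"]
    list(ins = ins, matched = matched)
  })
  need <- vapply(seq_len(L + 1L), function(s0)
    max(vapply(parts, function(p) length(p$ins[[s0]]), integer(1))), integer(1))

  build_row <- function(matched, ins) {
    out <- character(0)
    for (s0 in seq_len(L + 1L)) {
      blk <- ins[[s0]]
      out <- c(out, blk, rep("-", need[s0] - length(blk)))
      if (s0 <= L) out <- c(out, matched[s0])
    }
    paste(out, collapse = "")
  }
  ref_row <- build_row(ref_chars, rep(list(character(0)), L + 1L))
  rows <- vapply(parts, function(p) build_row(p$matched, p$ins), "")
  msa(c(ref$id, records$id), c(ref_row, rows))
}

# coerce a one-row data frame / list to a record list(id, sequence)
as_record <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L, all(c("id", "sequence") %in% names(x)))
    x <- as.list(x)
  }
  stopifnot(is.list(x), !is.null(x$id), !is.null(x$sequence))
  x
}
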