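#' Construct a protein multiple sequence alignment object
#'
#' @param ids Character vector of unique row identifiers.
#' @param seqs Character vector of equal-length aligned sequences; gaps are
#'   `-` (`.` is normalized to `-`).
#' @return An object of class `protein_msa`: a list with elements `ids`,
#'   `seqs` and `ncol` (the alignment length).
#' @export
msa <- function(ids, seqs) {
  stopifnot(is.character(ids), is.character(seqs), length(ids) == length(seqs))
  if (length(ids) == 0L) stop("empty input: alignment has no rows")
  if (anyDuplicated(ids))
    stop("duplicate row id(s): ",
         paste(sQuote(unique(ids[duplicated(ids)])), collapse = ", "))
  seqs <- toupper(gsub("\\.", "-", seqs))
  w <- unique(nchar(seqs))
  if (length(w) != 1L)
    stop("alignment-shape error: rows have unequal lengths (",
         paste(sort(w), collapse = ", "), ")")
  if (w == 0L) stop("empty input: alignment has zero columns")
  ok <- grepl(paste0("^[", paste(AA_LETTERS, collapse = ""), "X-]+$"), seqs)
  if (!all(ok))
    stop("illegal residues in aligned row(s): ",
         paste(sQuote(ids[!ok]), collapse = ", "))
  structure(list(ids = ids, seqs = seqs, ncol = w), class = "protein_msa")
}

#' @export
print.protein_msa <- function(x, ...) {
  cat("protein MSA:", length(x$ids), "rows x", x$ncol, "columns\n")
  invisible(x)
}

#' Remove gaps from aligned sequences
#'
#' @param x A `protein_msa` or a character vector of gapped sequences.
#' @return Character vector of ungapped sequences.
#' @export
degap <- function(x) {
  s <- if (inherits(x, "protein_msa")) x$seqs else x
  gsub("[.-]", "", s)
}

#' Read a Stockholm 1.0 alignment
#'
#' Annotation lines (`#...`) and the terminator (`//`) are ignored; rows
#' split across blocks are concatenated; `.` gaps are normalized to `-`.
#'
#' @param path Path to a Stockholm-format text file.
#' @return A [msa()] object.
#' @export
read_stockholm <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("Stockholm file not found: ", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  lines <- lines[!grepl("^\\s*(#|//|$)", lines)]
  if (length(lines) == 0L)
    stop("empty input: no sequence lines in '", path, "'")
  parts <- regmatches(lines, regexec("^(\\S+)\\s+(\\S+)\\s*$", lines))
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop("parse error: malformed Stockholm sequence line: ",
         sQuote(lines[bad[1]]))
  nm <- vapply(parts, `[`, "", 2L)
  sq <- vapply(parts, `[`, "", 3L)
  ids <- unique(nm)
  seqs <- vapply(ids, function(i) paste(sq[nm == i], collapse = ""), "")
  msa(ids, unname(seqs))
}

#' Read an aligned FASTA file as an MSA
#'
#' Like [read_fasta()] but gap characters are retained and all rows must
#' have equal length.
#'
#' @param path Path to an aligned (gapped) FASTA file.
#' @return A [msa()] object.
#' @export
read_aligned_fasta <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("empty input: no FASTA records in '", path, "'")
  rec_of <- cumsum(hdr)
  ids <- character(0); seqs <- character(0)
  for (r in seq_len(max(rec_of))) {
    lns <- which(rec_of == r)
    h <- sub("^>\\s*", "", lines[lns[1]])
    ids <- c(ids, sub("\\s.*$", "", h))
    seqs <- c(seqs, paste(toupper(gsub("\\s", "", lines[lns[-1]])), collapse = ""))
  }
  msa(ids, seqs)
}

#' Write an MSA as aligned FASTA
#'
#' @param x A [msa()] object.
#' @param path Output file path.
#' @param wrap_width Maximum characters per sequence line.
#' @return Invisibly, `path`.
#' @export
write_aligned_fasta <- function(x, path, wrap_width = 60L) {
  stopifnot(inherits(x, "protein_msa"))
  write_fasta(data.frame(id = x$ids, description = "", sequence = x$seqs,
                         stringsAsFactors = FALSE),
              path, wrap_width = wrap_width)
}
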