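#' Read protein sequences from a FASTA file
#'
#' Parses a protein FASTA file into a data frame of records.  The header
#' token before the first whitespace becomes the record `id`, the remainder
#' the `description`.  Sequences are upper-cased, whitespace and alignment
#' gaps are removed, a terminal stop (`*`) is stripped, and the ambiguity
#' codes `B`, `Z`, `U`, `O` are mapped to `X` with a warning.
#'
#' @param path Path to a FASTA text file.
#' @return A data frame with character columns `id`, `description` and
#'   `sequence`, one row per record.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a small test", "mghk*"), fa)
#' read_fasta(fa)
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("empty input: no FASTA records in '", path, "'")
  if (any(nzchar(trimws(lines[seq_len(which(hdr)[1] - 1)]))))
    stop("parse error: sequence data before the first '>' header in '", path, "'")

  rec_of <- cumsum(hdr)
  ids <- character(0); descs <- character(0); seqs <- character(0)
  n_ambig <- 0L
  legal <- paste0("^[", paste(AA_LETTERS, collapse = ""), "XBZUO*.-]*$")
  for (r in seq_len(max(rec_of))) {
    lns <- which(rec_of == r)
    h <- sub("^>\\s*", "", lines[lns[1]])
    ids <- c(ids, sub("\\s.*$", "", h))
    descs <- c(descs, if (grepl("\\s", h)) trimws(sub("^\\S+", "", h)) else "")
    chunks <- character(0)
    for (ln in lns[-1]) {
      s <- toupper(gsub("\\s", "", lines[ln]))
      if (!nzchar(s)) next
      if (!grepl(legal, s)) {
        bad <- unique(strsplit(gsub(legal_class(), "", s), "")[[1]])
        stop(sprintf("parse error at line %d: illegal character(s) %s",
                     ln, paste(sQuote(bad), collapse = ", ")))
      }
      chunks <- c(chunks, s)
    }
    s <- paste(chunks, collapse = "")
    s <- sub("\\*$", "", s)            # terminal stop
    if (grepl("\\*", s))
      stop("parse error: internal stop codon '*' in record '", ids[r], "'")
    s <- gsub("[.-]", "", s)           # records are unaligned: drop gaps
    n_ambig <- n_ambig + nchar(s) - nchar(gsub("[BZUO]", "", s))
    s <- gsub("[BZUO]", "X", s)
    if (!nzchar(s)) stop("empty sequence for record '", ids[r], "'")
    seqs <- c(seqs, s)
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate id(s) in FASTA: ", paste(sQuote(dup), collapse = ", "))
  }
  if (n_ambig > 0L)
    warning(n_ambig, " ambiguous residue(s) (B/Z/U/O) mapped to X")
  data.frame(id = ids, description = descs, sequence = seqs,
             stringsAsFactors = FALSE)
}

legal_class <- function() {
  paste0("[", paste(AA_LETTERS, collapse = ""), "XBZUO*.-]")
}

#' Write protein records to a FASTA file
#'
#' @param records Data frame with columns `id`, `sequence` and optionally
#'   `description`, as returned by [read_fasta()].
#' @param path Output file path.
#' @param wrap_width Maximum sequence characters per line (default 60).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, wrap_width = 60L) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)),
            wrap_width >= 1L)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    desc <- if ("description" %in% names(records)) records$description[i] else ""
    hdr <- if (nzchar(desc)) paste0(">", records$id[i], " ", desc)
           else paste0(">", records$id[i])
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = wrap_width)
    writeLines(c(hdr, substring(s, starts, pmin(starts + wrap_width - 1L, nchar(s)))),
               con)
  }
  invisible(path)
}

#' Validate a collection of protein records
#'
#' Checks the record invariants: non-empty unique ids, non-empty sequences
#' over the allowed alphabet (20 standard residues plus X).
#'
#' @param records Data frame of protein records.
#' @return Invisibly, `records`; errors otherwise.
#' @export
validate_records <- function(records) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  if (nrow(records) == 0L) return(invisible(records))
  if (any(!nzchar(records$id))) stop("record ids must be non-empty")
  if (anyDuplicated(records$id))
    stop("duplicate record id(s): ",
         paste(sQuote(unique(records$id[duplicated(records$id)])), collapse = ", "))
  if (any(!nzchar(records$sequence))) stop("record sequences must be non-empty")
  ok <- grepl(paste0("^[", paste(AA_LETTERS, collapse = ""), "X]+$"),
              records$sequence)
  if (!all(ok))
    stop("record(s) with illegal residues: ",
         paste(sQuote(records$id[!ok]), collapse = ", "))
  invisible(records)
}
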