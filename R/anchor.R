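VERDICT_LEVELS <- c("NO_HMM_HIT", "REJECTED_ANNOTATION", "NO_YGC", "NO_KD",
                    "MISPLACED", "CONFIRMED")

#' Define the catalytic-residue anchors of a reference methioninase
#'
#' Methioninase specificity rests on two conserved active-site stretches:
#' Tyr-Gly-Cys (`YGC`, positions 114-116 in the *P. putida* enzyme
#' numbering) and Lys-Asp (`KD`, positions 240-241).  The reference
#' sequence must carry both motifs at the stated 1-based positions.
#'
#' @param reference A protein record (list or one-row data frame with `id`
#'   and `sequence`).
#' @param motif1,motif1_start First motif and its 1-based start in the
#'   reference (defaults `"YGC"`, 114).
#' @param motif2,motif2_start Second motif and its start (defaults `"KD"`,
#'   240).
#' @return An object of class `reference_anchor`.
#' @export
reference_anchor <- function(reference, motif1 = "YGC", motif1_start = 114L,
                             motif2 = "KD", motif2_start = 240L) {
  ref <- as_record(reference)
  stopifnot(nzchar(motif1), nzchar(motif2),
            motif1_start >= 1L, motif2_start >= 1L)
  chk <- function(motif, start) {
    found <- substr(ref$sequence, start, start + nchar(motif) - 1L)
    if (found != motif)
      stop("anchor inconsistency: reference '", ref$id, "' has ",
           sQuote(found), " at position ", start, ", expected ",
           sQuote(motif))
  }
  chk(motif1, motif1_start)
  chk(motif2, motif2_start)
  structure(list(reference = ref,
                 motif1 = motif1, motif1_start = as.integer(motif1_start),
                 motif2 = motif2, motif2_start = as.integer(motif2_start)),
            class = "reference_anchor")
}

#' @export
print.reference_anchor <- function(x, ...) {
  cat("reference anchor on '", x$reference$id, "': ",
      x$motif1, "@", x$motif1_start, ", ",
      x$motif2, "@", x$motif2_start, "\n", sep = "")
  invisible(x)
}

#' Find all exact motif occurrences in a sequence
#'
#' Occurrences may overlap and are returned in ascending order of their
#' 1-based start positions.
#'
#' @param sequence A protein sequence string.
#' @param motif A non-empty residue string.
#' @return Integer vector of start positions (possibly empty).
#' @examples
#' find_motifs("YGCYGC", "YGC")
#' @export
find_motifs <- function(sequence, motif) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            is.character(motif), length(motif) == 1L)
  if (!nzchar(motif)) stop("argument error: motif must be non-empty")
  hits <- gregexpr(paste0("(?=", motif, ")"), sequence, perl = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

#' Classify one candidate against the reference anchors
#'
#' The staged decision of the screening funnel:
#' \enumerate{
#'   \item no occurrence of motif 1 (`YGC`) anywhere: `NO_YGC`;
#'   \item otherwise, no occurrence of motif 2 (`KD`): `NO_KD`;
#'   \item otherwise the candidate is globally aligned to the reference and
#'     the reference anchor positions are mapped into candidate
#'     coordinates; if every anchor column maps to a residue (no gap), the
#'     mapped positions are consecutive, and the candidate residues there
#'     spell the motifs: `CONFIRMED`; otherwise `MISPLACED`.
#' }
#' With `position_tolerance > 0`, a motif occurrence whose start lies
#' within that many residues of the mapped anchor start also confirms.
#'
#' @param candidate A protein record (list or one-row data frame).
#' @param anchor A [reference_anchor()].
#' @param substitution_matrix,gap_open,gap_extend Alignment parameters,
#'   passed to [global_align()].
#' @param position_tolerance Allowed offset between a motif occurrence and
#'   the mapped anchor position (default 0 = exact).
#' @return An object of class `screen_verdict`: a list with `id`, `status`,
#'   `motif1_positions`, `motif2_positions`, `anchor_mapped_1`,
#'   `anchor_mapped_2` and `bit_score` (`NA` unless filled by
#'   [screen_batch()]).
#' @export
classify_candidate <- function(candidate, anchor,
                               substitution_matrix = "BLOSUM62",
                               gap_open = 10, gap_extend = 3,
                               position_tolerance = 0L) {
  cand <- as_record(candidate)
  stopifnot(inherits(anchor, "reference_anchor"))
  v <- structure(list(id = cand$id, status = NA_character_,
                      motif1_positions = integer(0),
                      motif2_positions = integer(0),
                      anchor_mapped_1 = NA_integer_,
                      anchor_mapped_2 = NA_integer_,
                      bit_score = NA_real_),
                 class = "screen_verdict")
  v$motif1_positions <- find_motifs(cand$sequence, anchor$motif1)
  if (length(v$motif1_positions) == 0L) { v$status <- "NO_YGC"; return(v) }
  v$motif2_positions <- find_motifs(cand$sequence, anchor$motif2)
  if (length(v$motif2_positions) == 0L) { v$status <- "NO_KD"; return(v) }

  al <- global_align(anchor$reference$sequence, cand$sequence,
                     substitution_matrix = substitution_matrix,
                     gap_open = gap_open, gap_extend = gap_extend)
  check_anchor <- function(motif, start, occurrences) {
    idx <- start:(start + nchar(motif) - 1L)
    mapped <- al$column_map[idx]
    first <- mapped[[1L]]
    ok <- !anyNA(mapped) && all(diff(mapped) == 1L) &&
      substr(cand$sequence, mapped[1L], mapped[length(mapped)]) == motif
    if (!ok && position_tolerance > 0L && !is.na(first))
      ok <- any(abs(occurrences - first) <= position_tolerance)
    list(ok = ok, mapped_start = first)
  }
  c1 <- check_anchor(anchor$motif1, anchor$motif1_start, v$motif1_positions)
  c2 <- check_anchor(anchor$motif2, anchor$motif2_start, v$motif2_positions)
  v$anchor_mapped_1 <- c1$mapped_start
  v$anchor_mapped_2 <- c2$mapped_start
  v$status <- if (c1$ok && c2$ok) "CONFIRMED" else "MISPLACED"
  v
}

#' @export
print.screen_verdict <- function(x, ...) {
  cat("verdict for '", x$id, "': ", x$status, "\n", sep = "")
  invisible(x)
}

#' Screen a batch of candidates through the full funnel
#'
#' Applies [classify_candidate()] to every record, optionally gated by
#' profile-HMM hits: records whose `passed` flag is `FALSE` get status
#' `NO_HMM_HIT` and skip the motif stages.  The funnel counts report the
#' monotone candidate-reduction chain
#' `n_input >= n_hmm_pass >= n_with_ygc >= n_with_ygc_kd >= n_confirmed`.
#'
#' @param records Data frame of protein records.
#' @param anchor A [reference_anchor()].
#' @param hmm_hits Optional data frame from [hmm_screen()] with columns
#'   `id`, `bit_score`, `passed`.
#' @param substitution_matrix,gap_open,gap_extend,position_tolerance
#'   Passed to [classify_candidate()].
#' @return An object of class `mgl_screen`: a list with `verdicts` (one
#'   data-frame row per record: `id`, `status`, `bit_score`,
#'   `motif1_positions`, `motif2_positions`, `anchor_mapped_1`,
#'   `anchor_mapped_2`) and `funnel` (named integer vector).
#' @export
screen_batch <- function(records, anchor, hmm_hits = NULL,
                         substitution_matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 3,
                         position_tolerance = 0L) {
  stopifnot(is.data.frame(records), inherits(anchor, "reference_anchor"))
  if (nrow(records) > 0L) validate_records(records)
  if (!is.null(hmm_hits)) {
    stopifnot(is.data.frame(hmm_hits),
              all(c("id", "bit_score", "passed") %in% names(hmm_hits)))
    missing <- setdiff(records$id, hmm_hits$id)
    if (length(missing))
      stop("hmm_hits lacks record(s): ", paste(sQuote(missing), collapse = ", "))
  }
  verdicts <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    rec <- list(id = records$id[i], sequence = records$sequence[i])
    if (!is.null(hmm_hits)) {
      hit <- hmm_hits[match(rec$id, hmm_hits$id), ]
      if (!hit$passed) {
        verdicts[[i]] <- list(id = rec$id, status = "NO_HMM_HIT",
                              bit_score = hit$bit_score,
                              motif1_positions = "", motif2_positions = "",
                              anchor_mapped_1 = NA_integer_,
                              anchor_mapped_2 = NA_integer_)
        next
      }
    }
    v <- classify_candidate(rec, anchor,
                            substitution_matrix = substitution_matrix,
                            gap_open = gap_open, gap_extend = gap_extend,
                            position_tolerance = position_tolerance)
    verdicts[[i]] <- list(
      id = v$id, status = v$status,
      bit_score = if (is.null(hmm_hits)) NA_real_
                  else hmm_hits$bit_score[match(v$id, hmm_hits$id)],
      motif1_positions = paste(v$motif1_positions, collapse = ","),
      motif2_positions = paste(v$motif2_positions, collapse = ","),
      anchor_mapped_1 = v$anchor_mapped_1,
      anchor_mapped_2 = v$anchor_mapped_2)
  }
  vdf <- do.call(rbind, lapply(verdicts, function(v)
    data.frame(v, stringsAsFactors = FALSE)))
  if (is.null(vdf))
    vdf <- data.frame(id = character(0), status = character(0),
                      bit_score = numeric(0), motif1_positions = character(0),
                      motif2_positions = character(0),
                      anchor_mapped_1 = integer(0),
                      anchor_mapped_2 = integer(0))
  st <- vdf$status
  funnel <- c(
    n_input = nrow(vdf),
    n_hmm_pass = sum(st != "NO_HMM_HIT"),
    n_with_ygc = sum(!st %in% c("NO_HMM_HIT", "NO_YGC")),
    n_with_ygc_kd = sum(!st %in% c("NO_HMM_HIT", "NO_YGC", "NO_KD")),
    n_confirmed = sum(st == "CONFIRMED"))
  if (any(diff(funnel) > 0L))
    stop("internal error: funnel counts are not monotone")  # invariant
  structure(list(verdicts = vdf, funnel = funnel), class = "mgl_screen")
}

#' @export
print.mgl_screen <- function(x, ...) {
  cat("methioninase screen of", x$funnel[["n_input"]], "candidate(s)\n")
  cat(sprintf("  %-14s %d\n", names(x$funnel), x$funnel), sep = "")
  invisible(x)
}

#' @export
summary.mgl_screen <- function(object, ...) {
  tab <- table(factor(object$verdicts$status, levels = VERDICT_LEVELS))
  cat("verdict counts:\n")
  print(tab[tab > 0 | names(tab) == "CONFIRMED"])
  invisible(tab)
}

#' Demote candidates whose external annotation disagrees
#'
#' Re-casts the manual annotation-consensus retention step (database
#' cross-checks of HMM hits) as a table-driven filter: verdicts whose id
#' carries a label outside `accepted_labels` are demoted to
#' `REJECTED_ANNOTATION`.  Ids absent from the table are left untouched
#' (permissive default).
#'
#' @param verdicts Verdict data frame (from `screen_batch()$verdicts`).
#' @param annotation_table Data frame with columns `id` and `label`.
#' @param accepted_labels Labels that keep a candidate (default
#'   `"methionine-gamma-lyase"`).
#' @return The verdict data frame with demoted statuses.
#' @export
apply_annotation_filter <- function(verdicts, annotation_table,
                                    accepted_labels = "methionine-gamma-lyase") {
  stopifnot(is.data.frame(verdicts), "id" %in% names(verdicts),
            "status" %in% names(verdicts))
  if (!is.data.frame(annotation_table) ||
      !all(c("id", "label") %in% names(annotation_table)))
    stop("schema error: annotation table needs columns 'id' and 'label'")
  bad <- annotation_table$id[!annotation_table$label %in% accepted_labels]
  verdicts$status[verdicts$id %in% bad] <- "REJECTED_ANNOTATION"
  verdicts
}
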