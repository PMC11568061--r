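TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus",
               "species")

#' Parse a 7-rank semicolon lineage string
#'
#' GTDB-style rank prefixes (`d__`, `p__`, ...) are stripped if present.
#'
#' @param lineage Character vector of lineage strings
#'   (`domain;phylum;class;order;family;genus;species`).
#' @return A character matrix with one row per lineage and the seven rank
#'   columns.
#' @export
parse_lineage <- function(lineage) {
  parts <- strsplit(lineage, ";")
  bad <- which(lengths(parts) != 7L)
  if (length(bad))
    stop("lineage error: expected 7 semicolon-delimited ranks, got ",
         lengths(parts)[bad[1]], " in ", sQuote(lineage[bad[1]]))
  m <- t(vapply(parts, function(p) sub("^\\s*[a-z]__", "", trimws(p)),
                character(7)))
  colnames(m) <- TAX_RANKS
  m
}

#' Summarize screening outcomes per taxon at a rank
#'
#' Groups records by their taxon at `rank` and reports, per taxon, the
#' number of positives (status `CONFIRMED`), the total, the within-taxon
#' fraction, and the taxon's share of all positives -- the numbers behind
#' per-phylum prevalence pie charts.  When no record is positive the
#' shares are reported as 0 and the result carries the attribute
#' `share_defined = FALSE`.
#'
#' @param verdicts Verdict data frame (from `screen_batch()$verdicts`),
#'   or any data frame with `id` and `status`.
#' @param taxonomy_table Data frame with columns `id` and `lineage`
#'   covering every verdict id.
#' @param rank One of domain, phylum, class, order, family, genus,
#'   species.
#' @return Data frame with columns `rank`, `taxon`, `n_positive`,
#'   `n_total`, `fraction`, `share_of_positives`, sorted by `n_positive`
#'   descending then `taxon` ascending.
#' @export
summarize_by_rank <- function(verdicts, taxonomy_table, rank = "phylum") {
  stopifnot(is.data.frame(verdicts), all(c("id", "status") %in% names(verdicts)),
            is.data.frame(taxonomy_table),
            all(c("id", "lineage") %in% names(taxonomy_table)))
  rank <- match.arg(rank, TAX_RANKS)
  missing <- setdiff(verdicts$id, taxonomy_table$id)
  if (length(missing))
    stop("missing taxonomy for id(s): ",
         paste(sQuote(missing), collapse = ", "))
  lin <- parse_lineage(taxonomy_table$lineage)
  taxon <- lin[match(verdicts$id, taxonomy_table$id), rank]
  pos <- verdicts$status == "CONFIRMED"
  taxa <- sort(unique(taxon))
  n_total <- vapply(taxa, function(t) sum(taxon == t), integer(1))
  n_positive <- vapply(taxa, function(t) sum(pos & taxon == t), integer(1))
  tot_pos <- sum(n_positive)
  out <- data.frame(rank = rank, taxon = taxa,
                    n_positive = n_positive, n_total = n_total,
                    fraction = n_positive / n_total,
                    share_of_positives = if (tot_pos > 0) n_positive / tot_pos
                                         else rep(0, length(taxa)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_positive, out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "share_defined") <- tot_pos > 0
  out
}

#' Collapse per-record verdicts to per-genome positives
#'
#' A genome counts as positive if any of its records is `CONFIRMED`;
#' multiple hits in one genome count once.
#'
#' @param verdicts Verdict data frame with `id` and `status`.
#' @param record_to_genome Data frame with columns `id` and `genome`
#'   covering every verdict id.
#' @return Data frame with columns `genome` and logical `positive`.
#' @export
genome_level_rollup <- function(verdicts, record_to_genome) {
  stopifnot(is.data.frame(verdicts), all(c("id", "status") %in% names(verdicts)),
            is.data.frame(record_to_genome),
            all(c("id", "genome") %in% names(record_to_genome)))
  missing <- setdiff(verdicts$id, record_to_genome$id)
  if (length(missing))
    stop("mapping error: no genome for id(s): ",
         paste(sQuote(missing), collapse = ", "))
  genome <- record_to_genome$genome[match(verdicts$id, record_to_genome$id)]
  pos <- verdicts$status == "CONFIRMED"
  genomes <- unique(genome)
  data.frame(genome = genomes,
             positive = vapply(genomes, function(g) any(pos[genome == g]),
                               logical(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a per-taxon annotation table for tree decoration
#'
#' Emits the plain-text (taxon, n_positive, n_total) table that external
#' tree-annotation tools (e.g. pie-chart decorations) consume.
#'
#' @param summaries Output of [summarize_by_rank()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_itol_annotation <- function(summaries, path) {
  stopifnot(is.data.frame(summaries),
            all(c("taxon", "n_positive", "n_total") %in% names(summaries)))
  write_table(summaries[, c("taxon", "n_positive", "n_total")], path)
}
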