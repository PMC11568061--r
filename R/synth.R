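# Swiss-Prot-like average amino-acid frequencies, used to give the
# synthetic reference a typical bacterial composition
TYPICAL_AA_FREQ <- c(
  A = 0.0825, C = 0.0137, D = 0.0545, E = 0.0675, F = 0.0386,
  G = 0.0707, H = 0.0227, I = 0.0596, K = 0.0584, L = 0.0966,
  M = 0.0242, N = 0.0406, P = 0.0470, Q = 0.0393, R = 0.0553,
  S = 0.0656, T = 0.0534, V = 0.0687, W = 0.0108, Y = 0.0292)

# residues that can never take part in either catalytic motif; used when
# rewriting accidental motif copies
NON_MOTIF_AA <- setdiff(AA_LETTERS, c("Y", "G", "C", "K", "D"))

# Rewrite accidental occurrences of `motifs` outside `keep_ranges`
# (list of c(start, end)) by replacing one residue of each occurrence with
# a residue that cannot participate in any motif.  Keeps the generated
# classes faithful to their truth labels.
scrub_motifs <- function(sequence, motifs, keep_ranges = list()) {
  chars <- strsplit(sequence, "")[[1]]
  protected <- logical(length(chars))
  for (r in keep_ranges) protected[r[1]:r[2]] <- TRUE
  repeat {
    hit <- NULL
    for (m in motifs) {
      for (p in find_motifs(paste(chars, collapse = ""), m)) {
        span <- p:(p + nchar(m) - 1L)
        if (!any(protected[span])) { hit <- span; break }
      }
      if (!is.null(hit)) break
    }
    if (is.null(hit)) break
    chars[hit[1L]] <- sample(NON_MOTIF_AA, 1L)
  }
  paste(chars, collapse = "")
}

#' Deterministic synthetic reference methioninase
#'
#' A synthetic stand-in for the *P. putida* reference enzyme, constructed
#' once (fixed internal seed) to the characteristics the screen assumes:
#' 398 residues, sequence-predicted mass within 43.0 +/- 0.15 kDa, the
#' catalytic `YGC` stretch at positions 114-116 and `KD` at 240-241, and
#' exactly one occurrence of each motif.  It is a synthetic sequence, not
#' the real enzyme; it defines the coordinate frame and composition of the
#' synthetic screening sets.
#'
#' @return A protein record (list with `id`, `description`, `sequence`).
#' @export
synthetic_reference <- function() {
  with_seed(1328L, {
    L <- 398L
    chars <- sample(AA_LETTERS, L, replace = TRUE, prob = TYPICAL_AA_FREQ)
    chars[114:116] <- c("Y", "G", "C")
    chars[240:241] <- c("K", "D")
    keep <- list(c(114L, 116L), c(240L, 241L))
    s <- scrub_motifs(paste(chars, collapse = ""), c("YGC", "KD"), keep)
    chars <- strsplit(s, "")[[1]]
    # nudge composition until the predicted mass sits at ~43 kDa
    anchored <- c(114:116, 240:241)
    free <- setdiff(seq_len(L), anchored)
    mass <- protein_mass(paste(chars, collapse = ""))
    for (iter in seq_len(5000L)) {
      if (abs(mass - 43000) <= 150) break
      i <- sample(free, 1L)
      old <- chars[i]
      cand <- if (mass > 43000) "G" else "W"
      if (old == cand) next
      trial <- chars; trial[i] <- cand
      ts <- paste(trial, collapse = "")
      # G can complete a YGC; reject swaps that mint a new motif copy
      if (length(find_motifs(ts, "YGC")) != 1L ||
          length(find_motifs(ts, "KD")) != 1L) next
      new_mass <- mass - AA_MASS[[old]] + AA_MASS[[cand]]
      if (abs(new_mass - 43000) < abs(mass - 43000)) {
        chars <- trial; mass <- new_mass
      }
    }
    list(id = "synthetic_MGL_reference",
         description = paste("synthetic methionine gamma-lyase reference",
                             "(398 aa, YGC@114, KD@240)"),
         sequence = paste(chars, collapse = ""))
  })
}

#' Configuration for a synthetic screening set
#'
#' The defaults are the conditions under which funnel fidelity is
#' assessed: five records per class and a 2\% per-site substitution rate
#' for the family-derived classes.  Lineage weights default to the
#' phylum proportions reported for confirmed methioninases
#' (Proteobacteria 50\%, Firmicutes 29\%, Firmicutes_A 13\%, remainder
#' Fusobacteriota).
#'
#' @param n_true Count of anchor-consistent true homologs.
#' @param n_no_ygc,n_no_kd,n_misplaced Decoy counts per class.
#' @param n_background Count of unrelated background proteins.
#' @param mutation_rate Per-site substitution probability outside the
#'   protected anchor positions, in `[0, 1]`.
#' @param seed Integer RNG seed; all randomness in a generated set flows
#'   from it.
#' @param phyla Data frame with columns `lineage` (7-rank semicolon
#'   strings) and `weight` (sampling weights, positive sum).
#' @param background_freqs Length-20 residue frequency vector for the
#'   background class (default uniform).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_true = 5L, n_no_ygc = 5L, n_no_kd = 5L,
                         n_misplaced = 5L, n_background = 5L,
                         mutation_rate = 0.02, seed = 1L,
                         phyla = default_phyla(),
                         background_freqs = rep(1 / 20, 20)) {
  counts <- c(n_true, n_no_ygc, n_no_kd, n_misplaced, n_background)
  stopifnot(all(counts >= 0L), mutation_rate >= 0, mutation_rate <= 1,
            is.data.frame(phyla), all(c("lineage", "weight") %in% names(phyla)),
            sum(phyla$weight) > 0, all(phyla$weight >= 0),
            length(background_freqs) == 20L, all(background_freqs >= 0))
  structure(list(n_true = as.integer(n_true), n_no_ygc = as.integer(n_no_ygc),
                 n_no_kd = as.integer(n_no_kd),
                 n_misplaced = as.integer(n_misplaced),
                 n_background = as.integer(n_background),
                 mutation_rate = mutation_rate, seed = as.integer(seed),
                 phyla = phyla,
                 background_freqs = background_freqs / sum(background_freqs)),
            class = "synth_config")
}

#' Default lineage pool for synthetic sets
#'
#' @return Data frame with GTDB-style 7-rank `lineage` strings and
#'   sampling `weight`s reflecting the reported phylum shares of confirmed
#'   methioninases.
#' @export
default_phyla <- function() {
  data.frame(
    lineage = c(
      "d__Bacteria;p__Proteobacteria;c__Gammaproteobacteria;o__Pseudomonadales;f__Porticoccaceae;g__HTCC2207;s__HTCC2207 sp002382445",
      "d__Bacteria;p__Firmicutes;c__Bacilli;o__Bacillales;f__Bacillaceae;g__Bacillus;s__Bacillus sp",
      "d__Bacteria;p__Firmicutes_A;c__Clostridia;o__Clostridiales;f__Clostridiaceae;g__Clostridium;s__Clostridium sp",
      "d__Bacteria;p__Fusobacteriota;c__Fusobacteriia;o__Fusobacteriales;f__Fusobacteriaceae;g__Fusobacterium;s__Fusobacterium sp"),
    weight = c(0.50, 0.29, 0.13, 0.08),
    stringsAsFactors = FALSE)
}

mutate_family_sequence <- function(ref_chars, protected, mutation_rate) {
  n <- length(ref_chars)
  mut <- runif(n) < mutation_rate & !protected
  for (i in which(mut))
    ref_chars[i] <- sample(setdiff(AA_LETTERS, ref_chars[i]), 1L)
  ref_chars
}

#' Generate mutants of the reference family
#'
#' Each of the `n` mutants substitutes every non-anchor position with
#' probability `mutation_rate` to a uniformly drawn different residue;
#' anchor positions are never touched, and substitutions that would mint
#' an extra copy of either motif are rewritten so each class stays
#' faithful to its truth label.
#'
#' @param reference Protein record carrying the anchors.
#' @param anchors A [reference_anchor()] consistent with `reference`.
#' @param n Number of mutants.
#' @param mutation_rate Per-site substitution probability.
#' @param seed Integer RNG seed.
#' @return Data frame of records with `truth_label = "true_mgl"`.
#' @export
generate_family <- function(reference, anchors, n, mutation_rate, seed) {
  ref <- as_record(reference)
  stopifnot(inherits(anchors, "reference_anchor"), n >= 0L,
            mutation_rate >= 0, mutation_rate <= 1)
  if (!identical(anchors$reference$sequence, ref$sequence))
    reference_anchor(ref, anchors$motif1, anchors$motif1_start,
                     anchors$motif2, anchors$motif2_start)  # errors if violated
  keep <- anchor_ranges(anchors)
  ref_chars <- strsplit(ref$sequence, "")[[1]]
  protected <- logical(length(ref_chars))
  for (r in keep) protected[r[1]:r[2]] <- TRUE
  with_seed(seed, {
    seqs <- vapply(seq_len(n), function(k) {
      s <- mutate_family_sequence(ref_chars, protected, mutation_rate)
      scrub_motifs(paste(s, collapse = ""),
                   c(anchors$motif1, anchors$motif2), keep)
    }, "")
    make_records("true_mgl", seqs)
  })
}

anchor_ranges <- function(anchors) {
  list(c(anchors$motif1_start, anchors$motif1_start + nchar(anchors$motif1) - 1L),
       c(anchors$motif2_start, anchors$motif2_start + nchar(anchors$motif2) - 1L))
}

make_records <- function(label, seqs) {
  n <- length(seqs)
  if (n == 0L)
    return(data.frame(id = character(0), description = character(0),
                      sequence = character(0), truth_label = character(0),
                      stringsAsFactors = FALSE))
  data.frame(id = sprintf("%s_%03d", label, seq_len(n)),
             description = "", sequence = seqs, truth_label = label,
             stringsAsFactors = FALSE)
}

#' Generate decoy or background records
#'
#' Decoy classes emulate the false-positive structure of the screen:
#' \describe{
#'   \item{`no_ygc`}{family mutants whose anchor Cys is replaced by His
#'     (the mutation known to abolish methioninase activity), leaving no
#'     `YGC` anywhere;}
#'   \item{`no_kd`}{family mutants with the anchor Lys replaced by Ala,
#'     leaving no `KD` anywhere;}
#'   \item{`misplaced`}{family mutants whose `YGC` is removed at the
#'     anchor and re-inserted at least 30 residues away (`KD` intact), so
#'     only the positional check can reject them;}
#'   \item{`background`}{i.i.d. sequences drawn from `background_freqs`,
#'     length uniform in 300-500, with no `YGC` occurrence.}
#' }
#'
#' @param reference,anchors,mutation_rate,seed As in [generate_family()].
#' @param kind One of `"no_ygc"`, `"no_kd"`, `"misplaced"`, `"background"`.
#' @param n Number of records.
#' @param background_freqs Residue frequencies for the background class.
#' @return Data frame of records with `truth_label = "decoy_<kind>"`
#'   (or `"background"`).
#' @export
generate_decoys <- function(reference, anchors, kind, n, mutation_rate, seed,
                            background_freqs = rep(1 / 20, 20)) {
  kind <- match.arg(kind, c("no_ygc", "no_kd", "misplaced", "background"))
  stopifnot(n >= 0L)
  ref <- as_record(reference)
  keep <- anchor_ranges(anchors)
  ref_chars <- strsplit(ref$sequence, "")[[1]]
  protected <- logical(length(ref_chars))
  for (r in keep) protected[r[1]:r[2]] <- TRUE
  m1 <- anchors$motif1_start; m2 <- anchors$motif2_start
  motifs <- c(anchors$motif1, anchors$motif2)

  with_seed(seed, {
    if (kind == "background") {
      seqs <- vapply(seq_len(n), function(k) {
        L <- sample(300:500, 1L)
        s <- paste(sample(AA_LETTERS, L, replace = TRUE,
                          prob = background_freqs), collapse = "")
        scrub_motifs(s, anchors$motif1)   # must fail the YGC stage
      }, "")
      return(make_records("background", seqs))
    }
    seqs <- vapply(seq_len(n), function(k) {
      s <- mutate_family_sequence(ref_chars, protected, mutation_rate)
      if (kind == "no_ygc") {
        s[m1 + 2L] <- "H"                       # Cys -> His
        keep_k <- keep[2]
      } else if (kind == "no_kd") {
        s[m2] <- "A"                            # Lys -> Ala
        keep_k <- keep[1]
      } else {                                  # misplaced
        s[m1:(m1 + 2L)] <- sample(NON_MOTIF_AA, 3L, replace = TRUE)
        pool <- setdiff(seq_len(length(s) - 2L),
                        c((m1 - 32L):(m1 + 32L), (m2 - 2L):(m2 + 2L)))
        at <- sample(pool, 1L)
        s[at:(at + 2L)] <- c("Y", "G", "C")
        keep_k <- c(list(c(at, at + 2L)), keep[2])
      }
      scrub_motifs(paste(s, collapse = ""), motifs, keep_k)
    }, "")
    make_records(paste0("decoy_", kind), seqs)
  })
}

#' Generate a full labelled screening set
#'
#' Concatenates the five classes in shuffled order, assigns every record a
#' lineage drawn from the configured phylum weights, and returns the
#' records together with a truth table.  Deterministic given
#' `config$seed`.
#'
#' @param config A [synth_config()].
#' @param reference Protein record carrying the anchors (default
#'   [synthetic_reference()]).
#' @param anchors A [reference_anchor()] on `reference` (default anchors).
#' @return A list with `records` (data frame incl. `taxonomy` and
#'   `truth_label` columns) and `truth` (data frame `id`, `truth_label`,
#'   `lineage`).
#' @export
generate_screen_set <- function(config, reference = synthetic_reference(),
                                anchors = reference_anchor(reference)) {
  stopifnot(inherits(config, "synth_config"))
  total <- config$n_true + config$n_no_ygc + config$n_no_kd +
    config$n_misplaced + config$n_background
  if (total == 0L) stop("empty input: all class counts are zero")
  sub_seeds <- with_seed(config$seed, sample.int(.Machine$integer.max - 1L, 6L))
  parts <- list(
    generate_family(reference, anchors, config$n_true,
                    config$mutation_rate, sub_seeds[1]),
    generate_decoys(reference, anchors, "no_ygc", config$n_no_ygc,
                    config$mutation_rate, sub_seeds[2]),
    generate_decoys(reference, anchors, "no_kd", config$n_no_kd,
                    config$mutation_rate, sub_seeds[3]),
    generate_decoys(reference, anchors, "misplaced", config$n_misplaced,
                    config$mutation_rate, sub_seeds[4]),
    generate_decoys(reference, anchors, "background", config$n_background,
                    config$mutation_rate, sub_seeds[5],
                    background_freqs = config$background_freqs))
  records <- do.call(rbind, parts)
  with_seed(sub_seeds[6], {
    records <- records[sample.int(nrow(records)), , drop = FALSE]
    records$taxonomy <- sample(config$phyla$lineage, nrow(records),
                               replace = TRUE, prob = config$phyla$weight)
  })
  rownames(records) <- NULL
  truth <- data.frame(id = records$id, truth_label = records$truth_label,
                      lineage = records$taxonomy, stringsAsFactors = FALSE)
  list(records = records, truth = truth)
}

#' Expected verdict status for a truth label
#'
#' @param truth_label Truth label(s) from a generated set.
#' @param hmm_stage Whether the HMM capture stage is in force (background
#'   records then fail there instead of at the YGC stage).
#' @return Character vector of expected `screen_batch()` statuses.
#' @export
expected_status <- function(truth_label, hmm_stage = FALSE) {
  map <- c(true_mgl = "CONFIRMED", decoy_no_ygc = "NO_YGC",
           decoy_no_kd = "NO_KD", decoy_misplaced = "MISPLACED",
           background = if (hmm_stage) "NO_HMM_HIT" else "NO_YGC")
  unname(map[truth_label])
}
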