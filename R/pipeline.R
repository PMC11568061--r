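#' Configuration for a full screening run
#'
#' Validates paths and run constants up front (fail fast), so a broken
#' configuration never starts a partial run.  Defaults carry the original
#' screen's constants: HMM capture threshold 150 bits, `YGC` at 114 and
#' `KD` at 240 on the reference, BLOSUM62 with gap open 10 / extend 3.
#'
#' @param candidates Path to the candidate protein FASTA.
#' @param reference Path to the single-record reference FASTA.
#' @param out_dir Output directory (created if needed).
#' @param seed_msa Optional Stockholm or aligned-FASTA seed alignment used
#'   to build the capture profile.
#' @param hmm_profile Optional HMMER3 ASCII profile (alternative to
#'   `seed_msa`).
#' @param taxonomy Optional taxonomy TSV (`id`, `lineage`).
#' @param annotation Optional annotation TSV (`id`, `label`).
#' @param hmm_threshold Bit-score capture threshold (default 150; `-Inf`
#'   lets every record into the motif stages).
#' @param motif1,motif1_start,motif2,motif2_start Anchor definition.
#' @param substitution_matrix,gap_open,gap_extend Alignment parameters.
#' @param identity_denominator `"alignment"` or `"shorter"` (identity
#'   reports).
#' @param distance_correction `"none"` or `"poisson"` (tree distances).
#' @param accepted_labels Annotation labels that keep a candidate.
#' @param position_tolerance Anchor-position tolerance (default 0).
#' @param seed Integer seed; the single source of randomness for a run.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(candidates, reference, out_dir,
                            seed_msa = NULL, hmm_profile = NULL,
                            taxonomy = NULL, annotation = NULL,
                            hmm_threshold = 150,
                            motif1 = "YGC", motif1_start = 114L,
                            motif2 = "KD", motif2_start = 240L,
                            substitution_matrix = "BLOSUM62",
                            gap_open = 10, gap_extend = 3,
                            identity_denominator = "alignment",
                            distance_correction = "none",
                            accepted_labels = "methionine-gamma-lyase",
                            position_tolerance = 0L, seed = 1L) {
  need <- function(p, what) {
    if (!is.null(p) && !file.exists(p))
      stop("config error: ", what, " file not found: ", p)
    p
  }
  need(candidates, "candidates")
  need(reference, "reference")
  need(seed_msa, "seed alignment")
  need(hmm_profile, "HMM profile")
  need(taxonomy, "taxonomy")
  need(annotation, "annotation")
  if (!is.null(seed_msa) && !is.null(hmm_profile))
    stop("config error: give either seed_msa or hmm_profile, not both")
  stopifnot(is.numeric(hmm_threshold), length(hmm_threshold) == 1L,
            !is.na(hmm_threshold))
  identity_denominator <- match.arg(identity_denominator,
                                    c("alignment", "shorter"))
  distance_correction <- match.arg(distance_correction, c("none", "poisson"))
  structure(list(candidates = candidates, reference = reference,
                 out_dir = out_dir, seed_msa = seed_msa,
                 hmm_profile = hmm_profile, taxonomy = taxonomy,
                 annotation = annotation, hmm_threshold = hmm_threshold,
                 motif1 = motif1, motif1_start = as.integer(motif1_start),
                 motif2 = motif2, motif2_start = as.integer(motif2_start),
                 substitution_matrix = substitution_matrix,
                 gap_open = gap_open, gap_extend = gap_extend,
                 identity_denominator = identity_denominator,
                 distance_correction = distance_correction,
                 accepted_labels = accepted_labels,
                 position_tolerance = as.integer(position_tolerance),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full screening funnel
#'
#' Orchestrates capture, motif filtering, positional validation and the
#' downstream summaries, writing all artifacts into `config$out_dir`:
#' `hits.tsv` (when a profile is configured), `verdicts.tsv`,
#' `funnel.tsv`, `confirmed.fasta`, `identity.tsv` (confirmed hits vs the
#' reference), `summary_phylum.tsv` and `itol_annotation.txt` (when a
#' taxonomy is configured), `tree.nwk` (when at least two hits are
#' confirmed) and `manifest.tsv`.  Reruns with identical configuration
#' and inputs are byte-identical.  On any stage error the partial outputs
#' are removed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the [screen_batch()] result, the output
#'   `paths`, and the run `manifest` data frame.
#' @export
run_screen <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  out <- function(name) {
    p <- file.path(config$out_dir, name)
    written <<- c(written, p)
    p
  }
  ok <- FALSE
  on.exit(if (!ok) unlink(written))

  stage <- "read-inputs"
  res <- tryCatch({
    records <- read_fasta(config$candidates)
    ref_df <- read_fasta(config$reference)
    if (nrow(ref_df) != 1L)
      stop("reference FASTA must contain exactly one record")
    anchor <- reference_anchor(ref_df[1, ], config$motif1, config$motif1_start,
                               config$motif2, config$motif2_start)
    taxonomy <- if (!is.null(config$taxonomy))
      read_table(config$taxonomy, c("id", "lineage"))
    annotation <- if (!is.null(config$annotation))
      read_table(config$annotation, c("id", "label"))

    stage <- "hmm-capture"
    hits <- NULL
    if (!is.null(config$seed_msa) || !is.null(config$hmm_profile)) {
      hmm <- if (!is.null(config$hmm_profile)) {
        read_hmmer3_profile(config$hmm_profile)
      } else {
        al <- tryCatch(read_stockholm(config$seed_msa),
                       error = function(e) read_aligned_fasta(config$seed_msa))
        build_from_msa(al)
      }
      hits <- hmm_screen(hmm, records, threshold = config$hmm_threshold)
      write_table(hits, out("hits.tsv"))
    }

    stage <- "anchor-filter"
    scr <- screen_batch(records, anchor, hmm_hits = hits,
                        substitution_matrix = config$substitution_matrix,
                        gap_open = config$gap_open,
                        gap_extend = config$gap_extend,
                        position_tolerance = config$position_tolerance)
    if (!is.null(annotation))
      scr$verdicts <- apply_annotation_filter(scr$verdicts, annotation,
                                              config$accepted_labels)
    write_table(scr$verdicts, out("verdicts.tsv"))
    write_table(data.frame(stage = names(scr$funnel),
                           count = as.integer(scr$funnel)),
                out("funnel.tsv"))
    confirmed <- records[records$id %in%
                           scr$verdicts$id[scr$verdicts$status == "CONFIRMED"], ,
                         drop = FALSE]
    write_fasta(confirmed, out("confirmed.fasta"))

    stage <- "identity-report"
    if (nrow(confirmed) > 0L) {
      idrep <- do.call(rbind, lapply(seq_len(nrow(confirmed)), function(i) {
        al <- global_align(confirmed$sequence[i], anchor$reference$sequence,
                           substitution_matrix = config$substitution_matrix,
                           gap_open = config$gap_open,
                           gap_extend = config$gap_extend)
        data.frame(id_a = confirmed$id[i], id_b = anchor$reference$id,
                   identity_pct = percent_identity(
                     al, denominator = config$identity_denominator),
                   score = al$score, stringsAsFactors = FALSE)
      }))
      write_table(idrep, out("identity.tsv"))
    }

    stage <- "taxonomy-summary"
    if (!is.null(taxonomy)) {
      summ <- summarize_by_rank(scr$verdicts, taxonomy, rank = "phylum")
      write_table(summ, out("summary_phylum.tsv"))
      write_itol_annotation(summ, out("itol_annotation.txt"))
    }

    stage <- "phylogeny"
    if (nrow(confirmed) >= 2L) {
      aln <- reference_anchored_msa(ref_df[1, ], confirmed,
                                    substitution_matrix = config$substitution_matrix,
                                    gap_open = config$gap_open,
                                    gap_extend = config$gap_extend)
      # tree of the confirmed hits only; the reference row anchors the MSA
      sub <- msa(aln$ids[-1L], aln$seqs[-1L])
      d <- distance_matrix(sub, correction = config$distance_correction)
      write_newick(nj_tree(d), out("tree.nwk"))
    }

    stage <- "manifest"
    # out_dir is implied by the manifest's own location; echoing it would
    # break byte-identity of reruns into different directories
    cfg <- config[setdiff(names(config), "out_dir")]
    cfg <- cfg[!vapply(cfg, is.null, logical(1))]
    manifest <- data.frame(
      key = c("package", "version", names(cfg), names(scr$funnel)),
      value = c("mglscreen", as.character(utils::packageVersion("mglscreen")),
                vapply(cfg, function(v) paste(format(v), collapse = ","), ""),
                as.character(as.integer(scr$funnel))),
      stringsAsFactors = FALSE)
    write_table(manifest, out("manifest.tsv"))
    list(screen = scr, paths = written, manifest = manifest)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  ok <- TRUE
  invisible(res)
}

parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--"))
      stop("usage error: expected a --flag, got ", sQuote(a))
    key <- gsub("-", "_", substring(a, 3L))
    if (i == length(args) || startsWith(args[[i + 1L]], "--")) {
      flags[[key]] <- TRUE
      i <- i + 1L
    } else {
      flags[[key]] <- args[[i + 1L]]
      i <- i + 2L
    }
  }
  flags
}

num_flag <- function(flags, key, default) {
  v <- flags[[key]]
  if (is.null(v)) return(default)
  if (identical(tolower(v), "-inf")) return(-Inf)
  as.numeric(v)
}

SUBCOMMANDS <- c("simulate", "screen", "summarize", "tree", "assay")

#' Run a pipeline subcommand
#'
#' Thin command-line layer over the package functions; each subcommand is
#' runnable standalone on the others' outputs.  Logs go to standard
#' error; data only to files.
#'
#' \describe{
#'   \item{simulate}{`--out DIR [--seed N --n-true N --n-no-ygc N
#'     --n-no-kd N --n-misplaced N --n-background N --mutation-rate X]` --
#'     writes `records.fasta`, `truth.tsv`, `taxonomy.tsv`,
#'     `reference.fasta`, `seed_msa.fasta` into DIR.}
#'   \item{screen}{`--in FASTA --reference FASTA --out DIR [--seed-msa F |
#'     --hmm-profile F] [--hmm-threshold X --taxonomy F --annotation F
#'     --seed N]` -- runs [run_screen()].}
#'   \item{summarize}{`--verdicts TSV --taxonomy TSV --out TSV
#'     [--rank phylum]`.}
#'   \item{tree}{`--in ALIGNED_FASTA --out NEWICK [--correction none]`.}
#'   \item{assay}{`--curve-conc a,b,... --curve-abs a,b,... --a420 X
#'     --volume-ml X --minutes X --protein-mg X [--out TSV]`.}
#' }
#'
#' @param name Subcommand name.
#' @param args Character vector of command-line arguments.
#' @return Integer exit code: 0 on success, 1 on a stage error, 2 on a
#'   usage error.
#' @export
run_subcommand <- function(name, args = character(0)) {
  usage <- function() {
    message("usage: mglscreen <", paste(SUBCOMMANDS, collapse = "|"),
            "> [--flags]; see ?run_subcommand for flags")
  }
  if (length(name) != 1L || !name %in% SUBCOMMANDS) {
    message("unknown subcommand: ", paste(name, collapse = " "))
    usage()
    return(2L)
  }
  if ("--help" %in% args) { usage(); return(0L) }
  tryCatch({
    flags <- parse_flags(args)
    switch(name,
      simulate = cli_simulate(flags),
      screen = cli_screen(flags),
      summarize = cli_summarize(flags),
      tree = cli_tree(flags),
      assay = cli_assay(flags))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
}

cli_simulate <- function(flags) {
  if (is.null(flags$out)) stop("usage: simulate requires --out DIR")
  dir.create(flags$out, showWarnings = FALSE, recursive = TRUE)
  cfg <- synth_config(
    n_true = num_flag(flags, "n_true", 5L),
    n_no_ygc = num_flag(flags, "n_no_ygc", 5L),
    n_no_kd = num_flag(flags, "n_no_kd", 5L),
    n_misplaced = num_flag(flags, "n_misplaced", 5L),
    n_background = num_flag(flags, "n_background", 5L),
    mutation_rate = num_flag(flags, "mutation_rate", 0.02),
    seed = num_flag(flags, "seed", 1L))
  ref <- synthetic_reference()
  anchors <- reference_anchor(ref)
  set <- generate_screen_set(cfg, ref, anchors)
  write_fasta(set$records, file.path(flags$out, "records.fasta"))
  write_table(set$truth, file.path(flags$out, "truth.tsv"))
  write_table(data.frame(id = set$truth$id, lineage = set$truth$lineage),
              file.path(flags$out, "taxonomy.tsv"))
  write_fasta(data.frame(id = ref$id, description = ref$description,
                         sequence = ref$sequence),
              file.path(flags$out, "reference.fasta"))
  fam <- generate_family(ref, anchors, 8L, cfg$mutation_rate,
                         seed = cfg$seed + 101L)
  write_aligned_fasta(msa(fam$id, fam$sequence),
                      file.path(flags$out, "seed_msa.fasta"))
  message("simulate: wrote ", nrow(set$records), " records to ", flags$out)
}

cli_screen <- function(flags) {
  if (is.null(flags$`in`) || is.null(flags$reference) || is.null(flags$out))
    stop("usage: screen requires --in FASTA --reference FASTA --out DIR")
  cfg <- pipeline_config(
    candidates = flags$`in`, reference = flags$reference,
    out_dir = flags$out, seed_msa = flags$seed_msa,
    hmm_profile = flags$hmm_profile, taxonomy = flags$taxonomy,
    annotation = flags$annotation,
    hmm_threshold = num_flag(flags, "hmm_threshold", 150),
    seed = num_flag(flags, "seed", 1L))
  res <- run_screen(cfg)
  message("screen: funnel ",
          paste(res$screen$funnel, collapse = " -> "))
}

cli_summarize <- function(flags) {
  if (is.null(flags$verdicts) || is.null(flags$taxonomy) || is.null(flags$out))
    stop("usage: summarize requires --verdicts TSV --taxonomy TSV --out TSV")
  v <- read_table(flags$verdicts, c("id", "status"))
  tx <- read_table(flags$taxonomy, c("id", "lineage"))
  rank <- if (is.null(flags$rank)) "phylum" else flags$rank
  write_table(summarize_by_rank(v, tx, rank = rank), flags$out)
  message("summarize: wrote ", flags$out)
}

cli_tree <- function(flags) {
  if (is.null(flags$`in`) || is.null(flags$out))
    stop("usage: tree requires --in ALIGNED_FASTA --out NEWICK")
  al <- read_aligned_fasta(flags$`in`)
  corr <- if (is.null(flags$correction)) "none" else flags$correction
  write_newick(nj_tree(distance_matrix(al, correction = corr)), flags$out)
  message("tree: wrote ", flags$out)
}

cli_assay <- function(flags) {
  need <- c("curve_conc", "curve_abs", "a420", "volume_ml", "minutes",
            "protein_mg")
  miss <- need[vapply(need, function(k) is.null(flags[[k]]), logical(1))]
  if (length(miss))
    stop("usage: assay requires --",
         paste(gsub("_", "-", miss), collapse = " --"))
  nums <- function(s) as.numeric(strsplit(s, ",")[[1]])
  curve <- fit_standard_curve(nums(flags$curve_conc), nums(flags$curve_abs))
  amm <- ammonia_from_absorbance(curve, nums(flags$a420),
                                 as.numeric(flags$volume_ml))
  act <- specific_activity(amm$umol, as.numeric(flags$minutes),
                           as.numeric(flags$protein_mg))
  report <- data.frame(
    slope = curve$slope, intercept = curve$intercept,
    r_squared = curve$r_squared, ammonia_umol = act$ammonia_umol,
    units = act$units, specific_activity_u_per_mg = act$specific_activity,
    specific_activity_sd = act$specific_activity_sd)
  if (!is.null(flags$out)) write_table(report, flags$out)
  else write.table(report, sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("assay: specific activity %.4g U/mg", act$specific_activity))
}
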