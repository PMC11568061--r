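Package: mglscreen
Title: In Silico Screening of Methionine Gamma-Lyase from Protein Sequence Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A niche-aware screening funnel for methionine gamma-lyase
    (methioninase, EC 4.4.1.11) in large protein sequence sets such as
    predicted ORFs from metagenome assemblies.  Candidates are captured with a
    profile hidden Markov model built from a seed alignment (or loaded from a
    HMMER3 ASCII profile), filtered for the catalytic YGC and KD residue
    stretches, and validated by mapping both motifs onto their active-site
    positions in a reference enzyme via global pairwise alignment.  Confirmed
    hits are rolled up across a taxonomy, placed on a neighbor-joining
    phylogeny, and supported by enzyme-characterization calculations (ammonia
    standard curve, specific activity, sequence-predicted molecular mass).
    A synthetic-data generator produces labelled candidate sets (true
    homologs, motif-destroyed and motif-misplaced decoys, background
    proteins) so the whole funnel is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
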