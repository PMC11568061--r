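---
title: "Screening protein sets for methionine gamma-lyase: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening protein sets for methionine gamma-lyase: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mglscreen)
```

## The screening problem

Methionine gamma-lyase (methioninase, MGL, EC 4.4.1.11) is a
PLP-dependent enzyme that degrades L-methionine to 2-oxobutyrate,
methanethiol and ammonia in a single step.  It is of applied interest
(methionine-auxotrophic tumours) and of ecological interest (anaerobic
amino-acid catabolism, syntrophy with methanogens).  Finding it in
metagenome-scale protein sets is harder than it looks: profile models for
the family also capture cystathionine gamma-synthase and several other
members of the aspartate-aminotransferase superfamily that are nearly
identical in overall sequence but catalyse different reactions.
Annotation databases disagree with each other on exactly these
candidates.

What does discriminate the true enzyme is its active site.  Two short
conserved stretches are jointly diagnostic, in the numbering of the
*Pseudomonas putida* enzyme: Tyr114-Gly115-Cys116 (`YGC`), where the
cysteine is the key specificity residue (its mutation to histidine
essentially abolishes activity towards methionine), and Lys240-Asp241
(`KD`), which participates in forming the active-site pocket.  Close
homologs either lack one of the stretches or carry it at a different
structural position.

`mglscreen` implements this as an ordered candidate-reduction funnel:

1. **capture** — score every candidate against a profile HMM of the
   family and keep those at or above a bit-score threshold;
2. **presence** — keep candidates containing `YGC` anywhere; then keep
   those also containing `KD` anywhere;
3. **position** — globally align each survivor to the reference enzyme,
   transfer the reference anchor coordinates through the alignment, and
   confirm only candidates whose motifs sit exactly at the mapped
   positions;
4. **rollup** — summarize confirmed hits per taxon, build a
   neighbor-joining tree of the confirmed set, and support downstream
   enzyme characterization with standard-curve and specific-activity
   arithmetic.

The stage order (presence first, position second) is part of the design:
it reproduces the reported funnel semantics, and the intermediate counts
(`n_with_ygc`, `n_with_ygc_kd`) are only meaningful under this order.
Every run asserts the monotone chain
`n_input >= n_hmm_pass >= n_with_ygc >= n_with_ygc_kd >= n_confirmed`.

## The capture model

The profile HMM is a plan7-style model: match states with
position-specific emissions, insert states emitting background
frequencies, silent delete states, and the seven transition classes
(M→M, M→I, M→D, I→M, I→I, D→M, D→D).  Models can be built from a seed
alignment with `build_from_msa()` or loaded from a HMMER3 ASCII profile
with `read_hmmer3_profile()`.

Construction from a seed alignment uses the textbook recipe: columns
with gap fraction below 0.5 become match states; emissions and
transitions are Laplace-smoothed observed counts,
$P(a) = (c_a + \kappa)/(n + 20\kappa)$ with pseudocount $\kappa = 1$ by
default; the null model is the smoothed overall residue frequency of the
seed.  Scoring is in bits (log base 2) throughout, as log-odds against
the null: `viterbi_score()` for the best state path, `forward_score()`
for the sum over paths (always ≥ Viterbi).  All dynamic programming is
done in log space; unknown residues (`X`) contribute exactly 0 bits
against the null.  Both scorers are verified against exhaustive
enumeration of every state path on small models (up to 3 match states,
sequences up to length 4) at tolerances of 1e-9 (Viterbi) and 1e-6
(forward).

Two deliberate simplifications relative to the HMMER3 program itself:
scoring is single-hit and global (whole sequence against whole model) —
no multihit local envelopes, no MSV/forward filter heuristics, no
E-values.  The familiar capture threshold of 150 bits is kept as the
default constant for fidelity, but because the alignment mode differs it
is *not* numerically transferable from `hmmscan` output; for models
built from other seeds it should be recalibrated.  On the synthetic
study conditions the margin is enormous (family members score around
+800 bits, unrelated background proteins score deeply negative), so any
threshold in a ±500-bit window gives the same capture set; the tests
pin this behaviour rather than the specific constant.

## Positional validation

`global_align()` is an affine-gap global alignment (a gap run of length
$L$ costs `gap_open + (L - 1) * gap_extend`), computed through
Biostrings' Needleman–Wunsch/Gotoh implementation and checked against a
brute-force enumeration of all global alignments for short sequences.
Defaults are BLOSUM62 with gap open 10 and extend 3, echoing the
alignment parameters of the original screen (which used Kalign with
those penalties; the aligner differs, a documented fidelity caveat).

`classify_candidate()` maps the five reference anchor positions
(114-116, 240-241) into candidate coordinates through the alignment's
column map.  Confirmation requires, for each motif, that

* every anchor column maps to a candidate residue (no gap),
* the mapped positions are consecutive in the candidate (an insertion
  inside the motif rejects — the strictest reading of "same position"),
* the candidate residues at the mapped positions spell the motif.

Offsets are not tolerated by default (`position_tolerance = 0`); a
configurable tolerance accepts a motif occurrence starting within ±t of
the mapped anchor.  Extra motif occurrences elsewhere in the candidate
are recorded in the verdict but never confirm on their own.

Two ambiguities in the source material were resolved as follows.
First, the second motif is written `KD` while one description reads
"lysine 240 and asparagine 241"; since `D` is aspartate, `KD` =
Lys-Asp is used (consistent with "Asp241" elsewhere).  Second, the
identity denominator behind reported percent-identity values is not
stated; `percent_identity()` defaults to the BLAST-style convention
(identities over all alignment columns) with `"shorter"` available as
the alternative.

A multiple alignment of confirmed hits is produced by
`reference_anchored_msa()` as a star alignment around the reference
("once a gap, always a gap" merging on reference coordinates).  The
positional validation only ever needs candidate-to-reference coordinate
transfer, which pairwise alignment provides exactly; a progressive MSA
would add a guide-tree dependency without changing any verdict.

The manual cross-database annotation consensus of the original workflow
(CDD/BlastKOALA/HMMER web checks) is re-cast as a table-driven filter:
`apply_annotation_filter()` demotes candidates whose supplied label is
not in the accepted set, and leaves unannotated candidates untouched.

## Downstream summaries

`summarize_by_rank()` rolls verdicts up a 7-rank GTDB-style lineage
(rank prefixes are stripped), reporting per-taxon positives, totals,
within-taxon fractions and each taxon's share of all positives — the
quantities that back per-phylum prevalence charts.  When genomes rather
than ORFs are the counting unit, `genome_level_rollup()` collapses
multiple hits per genome to one.

The phylogeny of confirmed hits is distance-based: p-distances over
shared ungapped columns, optionally Poisson-corrected
($d = -\ln(1-p)$), followed by neighbor joining (via \pkg{ape}).  This
replaces the approximate-ML step of the original workflow; the
package's claims concern distribution and clustering structure, not
branch support, and NJ is exact on additive matrices — a property the
tests exercise by rebuilding random 4-8 taxon trees from their path
distances.  Negative NJ branch lengths (possible on non-additive input)
are clamped to zero with the deficit moved to the sibling edge, keeping
path lengths through the parent unchanged.  Ties in distances are left
to the standard implementation; identical sequences (distance 0) are
legal and end up as siblings.

## Enzyme-characterization arithmetic

The assay module reproduces the quantification math used for in-vitro
validation: an ordinary least-squares ammonia standard curve
(`fit_standard_curve()`, absorbance at 420 nm vs ammonium chloride in
the 0.01-0.4 mM range, assumed linear, unweighted), inversion of the
curve to micromoles (`ammonia_from_absorbance()`; mM × mL = µmol, with
clamping of negative concentrations and an extrapolation flag outside
the calibrated range), the unit definition (1 U = 1 µmol ammonia per
minute; `specific_activity()` reports U/mg, with mean ± SD over
replicates), and sequence-predicted molecular mass
(`protein_mass()`, average residue masses plus one water — average
rather than monoisotopic because the comparisons of interest are at
SDS-PAGE scale).  Mass is undefined for sequences containing `X`; that
is an error, not a guess.

## What the synthetic generator emulates

No external database is reachable from a test environment, so the
package carries a generator that reproduces the *structure* of the
screening input, with truth labels:

* **true homologs** — mutants of the reference with per-site
  substitution probability `mutation_rate` outside the five protected
  anchor residues;
* **`no_ygc` decoys** — family mutants with the anchor Cys116→His, the
  substitution known to destroy specificity: HMM-captured, motif-absent;
* **`no_kd` decoys** — anchor Lys240→Ala;
* **`misplaced` decoys** — `YGC` excised at the anchor and re-planted at
  least 30 residues away with `KD` intact, so only the positional stage
  can reject them;
* **background** — i.i.d. sequences (uniform residue frequencies by
  default, configurable), lengths uniform in 300-500.

Substitutions that would *mint* an accidental copy of either motif are
rewritten with residues that cannot participate in any motif; background
sequences are likewise kept free of `YGC`.  This class-consistency
scrubbing is what makes truth labels exact: each class fails at exactly
its designed stage, so perfect recovery is the correct expectation, not
an optimistic one.  The reference itself, `synthetic_reference()`, is a
deterministic synthetic stand-in (the real reference and supplementary
sequences are not redistributable here) constructed to the
characteristics the screen assumes: 398 residues, predicted mass within
43.0 ± 0.15 kDa (typical bacterial composition), anchors at 114 and
240, and exactly one occurrence of each motif.

Default conditions are five records per class with `mutation_rate`
0.02, and lineages drawn with weights 0.50/0.29/0.13/0.08 over
Proteobacteria, Firmicutes, Firmicutes_A and Fusobacteriota — the
reported phylum shares of confirmed methioninases.  All randomness in a
generated set flows from one integer seed; generators save and restore
the caller's RNG state.

What the generator does **not** emulate: insertions and deletions
within the family (true homologs are substitution-only), sequencing or
assembly error, compositional biases of real proteomes, genuinely
remote homologs near the capture threshold, and disagreeing annotation
labels.  Passing tests therefore demonstrate that the funnel's logic is
correct and its stages reject what they are designed to reject — not
that the 150-bit constant or the strict positional rule are optimal on
real metagenomes.

## Numerical choices and degenerate inputs

* Residue alphabet: the 20 standard letters plus `X`; `B/Z/U/O` are
  mapped to `X` on input with a warning.  All positions everywhere are
  1-based.
* Viterbi traceback ties are irrelevant to scores; where a tie-break
  matters (alignment traceback) the Biostrings convention applies, and
  only scores are contract-tested.
* Zero-probability transitions score `-Inf` cleanly; a sequence no path
  can emit scores `-Inf` rather than erroring.
* An alignment in which a pair of rows shares no ungapped column is a
  distance error (named pair), as is a Poisson correction at p ≥ 1.
* A flat standard curve (zero absorbance variance) is flagged
  `degenerate` with r² reported as 0; fewer than three points or a
  single distinct concentration are errors.
* Funnel counts on an empty record set are all zero, not an error.

## Problem sizes

The test suite and the acceptance script run the study conditions at
desk scale, chosen so the whole suite completes in well under a minute
of CPU: 25-record mixtures for funnel fidelity, 15-record mixtures over
10 seeds for recovery, a 1650-record screen for phylum shares, profile
models of length 398 (the reference family) and up to 3 match states
for the exhaustive oracles, alignments up to length 6 for the
brute-force alignment oracle, and 4-8 taxa for tree-recovery
properties.  The headline counts of a database-scale screen (thousands
of candidate ORFs) depend on external resources and are out of scope by
design; the package's correctness claims are the invariants and
oracle-equivalences above.

## Known limitations

* The capture stage is global single-hit; fragmentary ORFs (common in
  real metagenome assemblies) would be penalized for their missing
  model span.  Screening fragments requires a local-alignment capture
  stage, which is out of scope.
* The positional rule is strict by default; genuinely homologous
  enzymes with an insertion inside an anchor motif would be rejected
  (`MISPLACED`).  The `position_tolerance` knob relaxes the start
  offset but never the contiguity requirement.
* Percent identity depends on the denominator convention; both common
  conventions are implemented, and exact reproduction of third-party
  identity values may require trying either.
* The NJ tree carries no support values; it is a clustering summary,
  not a phylogenetic inference with uncertainty.
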