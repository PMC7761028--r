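---
title: "Methods: genome-wide WRKY family mining with wrkymine"
author: "wrkymine authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide WRKY family mining with wrkymine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wrkymine)
```

# Scope and model

WRKY proteins are one of the largest plant transcription-factor families.
Their defining feature is the WRKY domain, a roughly 60-residue DNA-binding
module consisting of the conserved heptapeptide `WRKYGQK` (with natural
variants at position 6) followed by a zinc finger whose four
metal-coordinating residues are either Cys-Cys-His-His (C2H2) or
Cys-Cys-His-Cys (C2HC).  The family is conventionally partitioned by domain
content and finger chemistry:

* **group I** — two WRKY domains;
* **group II** — one domain with a C2H2 finger, refined phylogenetically
  into subgroups IIa–IIe;
* **group III** — one domain with a C2HC finger.

WRKY factors bind the W-box element `(C/T)TGAC(C/T)` in target promoters;
group-IIa promoters additionally carry a conserved *double* W-box in which
two full W-boxes sit with their `TGAC` cores separated by exactly two
nucleotides (`TTGACTTTGAC(T/C)`).

`wrkymine` implements the full mining pipeline around this model:
annotation parsing, collapse of transcript redundancy to genomic loci,
domain detection, group/subgroup classification, neighbor-joining
phylogenies with bootstrap, EM motif discovery, promoter element scanning,
protein physico-chemical properties, and relative-expression analysis of
qPCR Ct tables — together with deterministic synthetic-data generators that
make every stage testable against planted ground truth.

# Domain detection

`findWrkyDomains()` reports **every** (including overlapping) occurrence of
a heptapeptide pattern; the default set `WRKYG[QKE]K` admits the common
Q→K/E variants and `wrkyPattern(strict = TRUE)` restricts to the invariant
`WRKYGQK`.  For each heptapeptide the scanner walks downstream cysteines
and anchors the first zinc finger whose first coordinating cysteine starts
within `maxGap` residues of the heptapeptide end.  Spacing windows:

| chemistry | pattern | default windows |
|---|---|---|
| C2H2 | C-X(n1)-C-X(n2)-H-X-H | n1 ∈ 4–7, n2 ∈ 22–23 |
| C2HC | C-X(n1)-C-X(n2)-H-X-C | n1 ∈ 4–8, n2 ∈ 22–28 |

The C2H2 windows are the classical ones; no published spacing exists for
the C2HC case, so we use a permissive superset of the C2H2 windows
(configurable).  `maxGap` defaults to 40 residues, which keeps the
heptapeptide-plus-finger composite within one ~60-residue domain plus
slack.  At a candidate cysteine the C2H2 interpretation is tried before
C2HC, so a hit is never ambiguously classed.  A hit is *complete* when
both parts are present; heptapeptides without a finger are retained as
evidence but never classify a protein.

Two auxiliary signals use declared heuristics rather than served
predictors: the leucine zipper is the first window with four leucines at
exact period 7 (`L-X6-L-X6-L-X6-L`), and nuclear localization signals are
maximal merged 10-residue windows containing at least four K/R residues — a
rule that detects classical basic patches such as `SSRKRKLESP` and is
trivially testable against a sliding-window oracle, unlike a neural
predictor.

# Locus collapse and classification

Genome annotations routinely list several transcripts per locus.
`dedupeByLocus()` clusters CDS-bearing transcripts by single-linkage CDS
overlap of at least 1 bp on the same contig and strand — the most inclusive
deterministic reading of "same genomic locus" — and keeps the longest
encoded protein as the locus representative (ties broken by protein id).
`buildCatalog()` then applies the family definition to each representative.
Loci whose representative has a heptapeptide but no zinc finger are
excluded by default; `keepPartial = TRUE` admits them with a
`partial_domain` flag (their group stays `unclassified`).

Subgroups IIa–IIe carry no simple sequence definition; they are
phylogenetic.  `assignSubgroups()` gives each group-II entry the label of
its nearest labeled reference leaf by patristic distance on a user-supplied
tree, with exact ties broken toward the reference sharing the longest exact
common substring with the query.  The reference panel must cover all five
subgroups (the Arabidopsis set is the natural choice).

# Alignment, distances, trees

The pairwise aligner is a standard global Needleman–Wunsch with affine
gaps (a gap of length L costs `gapOpen + (L-1)·gapExtend`), BLOSUM62
scores, and defaults `gapOpen = -10`, `gapExtend = -1`.  Traceback is
deterministic (diagonal > up > left on ties), and the affine kernel is
shared — via a precomputed column-pair score matrix — with the
profile–profile steps of `progressiveMsa()`, which aligns along a UPGMA
guide tree built from 3-mer distances.  Profile columns are
occupancy-weighted (gaps contribute zero mass), so conserved occupied
columns dominate the merge score.  The progressive aligner replaces an
external MSA tool because alignment quality is not this pipeline's
contribution; any externally aligned FASTA is accepted wherever an
alignment is expected.

`pdistance()` computes the mismatch proportion per pair over columns where
neither sequence is gapped (pairwise deletion), optionally with the Kimura
protein correction `d = -ln(1 - p - p²/5)`.  `njTree()` is a native
Saitou–Nei implementation with the Studier–Keppler Q criterion; ties on Q
break deterministically toward the lexicographically smallest canonical
label pair, and negative branch lengths are clamped to zero with the
deficit moved to the sibling branch so the joined pair's path length is
preserved.  `bootstrapTree()` resamples alignment columns (default 1000
replicates) and reports, for each internal bipartition of the full-data
tree, the percentage of replicate trees containing it; a single integer
seed makes the whole procedure bit-reproducible.  The independent `ape`
implementation is used only as a cross-check in the test suite, never as
the implementation.

# Promoter scanning

A promoter here is the up-to-3000-bp window immediately upstream of the
translational start on the coding strand; `extractPromoter()` truncates
(with a warning) at contig edges rather than dropping genes, and when a
locus has several isoforms the catalog's representative transcript anchors
the window, so each catalog row has exactly one promoter.  Hit offsets are
reported ATG-relative with −1 the base immediately upstream of the A of
ATG, matching the field's "−800 bp" phrasing.

The built-in element set is: W-box `YTGACY`, G-box `CACGTG`, GCC-box
`GCCGCC`, TCA-element (`CCATCTTTTT`, `TCAGAAGAGG`), MeJa-RE `CGTCA`, and
ERE (`ATTTCAAA`, `ATTTCATA`).  The two W-box spellings found in the
literature, (C/T)TGAC(C/T) written from either strand, expand to the same
IUPAC word and are implemented once.  Scanning counts **all** overlapping
matches (naive pattern-count semantics, oracle-tested); the default is
forward-strand only — the minimal declared choice, since strand settings
of the original promoter surveys are unstated — with `strandMode = "both"`
one flag away.  In both-strand mode a reverse-strand match of a
self-reverse-complementary pattern over an interval already matched
forward is suppressed, so palindromes (G-box) count once.
`findBipartiteWbox()` matches the 12-mer `YTGACYYTGACY`, which is exactly
two adjacent full W-boxes with two intervening bases.  Because per-gene
counts depend on those strand/overlap conventions, published per-gene
tables are compared through their column totals only.

# Motif discovery

`discoverMotifs()` is a MEME-style ZOOPS (zero-or-one occurrence per
sequence) expectation–maximization: for each candidate width (scanned in
steps of 2 over 6–50 by default), EM runs from the five substring seeds
that score best after a single E-step, and the converged model maximizing
information-content-per-column × expected-site-count is kept.  Numerical
choices: pseudocount 0.1 per PWM cell, background = 0-order input
frequencies, convergence `|Δlog-lik| < 1e-4` or 100 iterations.  Because
EM can lock onto a planted signal shifted by a residue or two, the final
site set is phase-refined over shifts of ±3 columns, keeping the shift
with the highest information content.  Found sites are masked with a
neutral symbol before the next motif is sought, so successive motifs are
distinct.  The ZOOPS-only choice reflects conserved domains being present
in at most one copy in most but not all family members; MEME's E-value
machinery is deliberately not reproduced, so motifs are compared by
content, not by index.

# Protein properties

`molecularWeight()` sums average residue masses plus one water
(18.0153 Da).  `netCharge()` is the Henderson–Hasselbalch sum over the
free termini and the D/E/C/Y/H/K/R side chains with Bjellqvist-style pKa
values, and `isoelectricPoint()` bisects it on pH 0–14 to a residual
charge below 1e-4 (reported to 2 decimals by default).  Average rather
than monoisotopic masses are used because theoretical masses quoted for
whole proteins are average-mass figures.

# qPCR relative expression

`deltaDeltaCt()` implements the Livak 2^-ddCt method with amplification
efficiency fixed at 2: per replicate, dCt = Ct(target) − Ct(reference);
ddCt subtracts the mean calibrator dCt at the same timepoint; folds are
summarized as mean ± SD on the fold scale.  This replicate-level
aggregation (calibrator averaged at the dCt stage, folds averaged
afterwards) is the common Livak practice; with noise-free input the
calibrator recovers exactly 1.  `anovaTukey()` runs one-way ANOVA with
Tukey HSD and derives a compact letter display by insert-and-absorb over
the significant pairs; the ANOVA defaults to the fold scale (a dCt-scale
analysis is a transformation away), and the letters agree with the
`multcomp` display on separated designs, which the tests verify.

# Synthetic data and what passing tests mean

The generators are the package's ground-truth instruments; all randomness
flows from one explicit seed per call and outputs are byte-reproducible.

* `simulateWrkyProteome()` plants complete domain units (two C2H2 units
  for group I, one C2H2 for II, one C2HC for III, none for decoys) on a
  background alphabet that excludes W, C, H and M, so planted signals are
  provably the only domain evidence and scanner precision/recall have an
  exact oracle.  Group-II members are point-mutated copies of five
  subgroup centroid domains, giving recoverable subgroup structure.
* `simulateGenomeWithLoci()` lays loci ≥ 5 kb apart on alternating
  strands, reverse-translates planted proteins with a fixed codon table,
  splits CDS over 2–3 exons at codon boundaries, derives isoforms by
  dropping trailing exons, and plants a motif-free promoter immediately
  upstream of each ATG — so locus clustering, representative choice,
  promoter extraction and group calls all have exact expected values.
* `simulatePromoters()` rejection-samples background base-by-base so no
  built-in motif occurs before planting, then places the requested
  elements with guard bands and re-verifies the realized counts, making
  planted counts exact; double W-boxes are placed at requested
  ATG-relative offsets.
* `simulateCtTable()` draws Ct values whose expected 2^-ddCt equals the
  requested folds, with Gaussian replicate noise.

These fixtures deliberately do **not** emulate realistic genome
composition, codon usage, UTR structure, overlapping genes, promoter GC
heterogeneity, or phylogenetic signal beyond the subgroup centroids.
Passing the closed-loop tests therefore demonstrates correctness of the
algorithms under their stated definitions, not robustness to the
annotation noise, diverged heptapeptides or profile-level domain evidence
found in real genomes — on real data, proteins whose domains diverge past
the declared patterns would be missed where a profile scanner might still
find them.

# Validation problem sizes

The test-suite and acceptance-script checks use: 200 random 3000-bp
promoters against a brute-force regex oracle; exhaustive-enumeration
alignment scores for sequences up to 8 residues; additive 4/5-taxon NJ
recovery plus 50 random 5-taxon matrices against an independent NJ
implementation; a 50-protein planted proteome (10 I / 20 II / 5 III / 15
decoys); 20 seeded EM runs on 20×200-residue sets with one mutation per
planted 8-mer copy (discovery run at the planted width); fold recovery at
effect sizes {25, 1.78, 1.5} with Ct noise SD 0.1; and 2000 null
simulations (3 groups × 3 replicates) for the ANOVA type-I error.  These
sizes keep each suite well under desk-scale minutes while leaving no
tolerance wider than the property being demonstrated.

# Known limitations

* Heptapeptide and finger matching is pattern-based; no profile-HMM or
  PROSITE-profile scoring, so genome-wide counts on real assemblies can
  differ from profile-based curation.
* The progressive aligner is a deliberately simple MUSCLE stand-in; for
  publication-grade trees, align externally and pass the alignment in.
* The distance model behind published NJ trees of this family is
  typically unstated; exact reproduction of such figures is out of scope.
* Fold-scale ANOVA on 2^-ddCt values inherits the skewness of the
  exponential transform at large effect sizes.
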