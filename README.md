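# wrkymine

Genome-wide mining and characterization of **WRKY transcription factors**
in plant genomes.

WRKY proteins form one of the largest plant transcription-factor families.
Each carries a ~60-residue WRKY domain — the conserved heptapeptide
`WRKYGQK` (or a close variant) followed by a zinc finger — and binds the
W-box promoter element `(C/T)TGAC(C/T)`. The family partitions into
**group I** (two domains), **group II** (one domain, C2H2 finger
Cys-X4-7-Cys-X22-23-His-X-His; subgroups IIa–IIe defined phylogenetically)
and **group III** (one domain, C2HC finger). Surveying a genome for this
family, classifying the members, and characterizing their promoters —
including the conserved *double W-box* `TTGACTTTGAC(T/C)`, two W-boxes
whose `TGAC` cores are spaced by exactly two nucleotides — is a standard
but fiddly multi-stage analysis. `wrkymine` packages the whole pipeline as
tested, deterministic building blocks for R users working on plant TF
families:

* **Identification** — FASTA/GFF3 parsing, collapse of redundant
  transcripts to unique genomic loci (single-linkage CDS overlap),
  domain scanning (`findWrkyDomains`), group classification
  (`buildCatalog`) and phylogenetic subgroup assignment
  (`assignSubgroups`).
* **Phylogenetics** — native affine-gap pairwise and progressive
  alignment, p-distances, Saitou–Nei neighbor joining and bootstrap
  supports (`njTree`, `bootstrapTree`), Newick I/O.
* **Promoters** — strand-aware extraction of the 3000 bp upstream of the
  ATG (`extractPromoter`), IUPAC element scanning with exact overlap
  semantics (`scanPromoter`, `countTable`), and the bipartite double
  W-box finder (`findBipartiteWbox`).
* **Motifs** — MEME-style ZOOPS expectation–maximization discovery
  (`discoverMotifs`) with MEME-format export.
* **Protein properties** — theoretical molecular weight and isoelectric
  point (`molecularWeight`, `isoelectricPoint`).
* **Expression** — Livak 2^-ΔΔCt fold changes from replicate Ct tables
  with one-way ANOVA + Tukey letters (`deltaDeltaCt`, `anovaTukey`).
* **Synthetic data** — seeded generators with ground-truth manifests
  (`simulateWrkyProteome`, `simulateGenomeWithLoci`,
  `simulatePromoters`, `simulateCtTable`) so every stage is testable
  without downloads.

See the methods vignette (`vignettes/wrkymine-methods.Rmd`) for the models,
conventions and numerical choices.

## Worked example

Simulate a small annotated genome with known ground truth, run the
identification funnel, and characterize promoters and expression:

```r
library(wrkymine)

sim <- simulateGenomeWithLoci(5, c(3, 2, 1, 2, 1),
                              c("II", "I", "III", "decoy", "II"), seed = 7)
cat1 <- runIdentify(sim$bundle)
#> identify funnel: 9 annotated transcripts -> 5 unique loci -> 4 WRKY-domain loci
cat1
#> WrkyCatalog with 4 entries
#>   groups:   I=1  II=2  III=1  unclassified=0
```

Nine annotated transcripts collapse to five loci; the four loci whose
representative protein carries a complete WRKY domain enter the catalog
with the planted group labels (the decoy locus is filtered out):

```r
catalogEntries(cat1)[, c("protein_id", "n_domains", "zf_class", "group")]
#>   protein_id n_domains zf_class group
#> 1  gene01.p1         1     C2H2    II
#> 2  gene02.p1         2     C2H2     I
#> 3  gene03.p1         1     C2HC   III
#> 4  gene05.p1         1     C2H2    II
```

Promoter scanning on a synthetic 3000-bp promoter with five planted
W-boxes, five MeJa-responsive elements and a double W-box planted 800 bp
upstream of the ATG:

```r
sp <- simulatePromoters(list(gA = c("W-box" = 5, "MeJa-RE" = 5)),
                        doubleWbox = list(gA = -800L), seed = 11)
reportCounts(countTable(sp$promoters))
#>    W-box G-box GCC-box TCA-element MeJa-RE ERE
#> gA     7     0       0           0       5   0
findBipartiteWbox(sp$promoters[["gA"]])[, c("motif", "offset", "match")]
#>          motif offset        match
#> 1 double-W-box   -800 TTGACTTTGACT
```

The W-box column reads 7 because the double W-box itself contributes two
W-box matches; the element is recovered at exactly offset −800 (−1 is the
base immediately upstream of the ATG).

Relative expression from a simulated Ct table with true fold changes
25 / 1.78 / 1.5 at three timepoints (Ct noise SD 0.1, triplicates):

```r
ct <- simulateCtTable(c(t30min = 25, t4h = 1.78, t24h = 1.5),
                      sd = 0.1, seed = 3)
fc <- runQpcr(ct)
fc[fc$condition == "treated",
   c("timepoint", "mean_fold", "sd_fold", "letter")]
#>   timepoint mean_fold    sd_fold letter
#> 2    t30min 24.981723 1.28996660      b
#> 4       t4h  1.809228 0.15756831      b
#> 6      t24h  1.556651 0.03481092      b
```

Each treated group recovers its planted fold change within replicate
noise and gets a Tukey letter distinct from its control (fold 1, letter
"a") at that timepoint.

A thin shell wrapper with `simulate` / `identify` / `tree` / `promoters` /
`motifs` / `props` / `qpcr` subcommands lives at
`inst/scripts/wrky-pipeline.R`.

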