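#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom Biostrings DNAStringSet AAStringSet
#' @importClassesFrom GenomicRanges GRangesList
#' @importFrom Rcpp sourceCpp
#' @useDynLib wrkymine, .registration = TRUE
NULL

#' WRKY domain search pattern
#'
#' Describes the sequence signals that define a WRKY domain: the conserved
#' heptapeptide (default \code{WRKYG[QKE]K}; strict mode restricts to
#' \code{WRKYGQK}) and the spacing windows of the two zinc-finger
#' chemistries.  The C2H2 finger follows C-X(4-7)-C-X(22-23)-H-X(1)-H; the
#' C2HC finger is matched with the permissive superset windows
#' C-X(4-8)-C-X(22-28)-H-X(1)-C.  \code{maxGap} bounds the distance (in
#' residues) between the end of the heptapeptide and the first coordinating
#' cysteine so that the composite stays within a single ~60-residue domain.
#'
#' @slot heptapeptides character vector of 7-residue patterns in bracket
#'   notation, OR-ed together.
#' @slot c2h2X1,c2h2X2 integer length-2 vectors, min/max spacer lengths of the
#'   C2H2 finger (C-X1-C-X2-H-X-H).
#' @slot c2hcX1,c2hcX2 integer length-2 vectors, min/max spacer lengths of the
#'   C2HC finger (C-X1-C-X2-H-X-C).
#' @slot maxGap single integer, maximum residues between heptapeptide end and
#'   the first zinc-finger cysteine.
#'
#' @seealso [wrkyPattern()] for the user-facing constructor.
#' @exportClass WrkyPattern
setClass("WrkyPattern", representation(
  heptapeptides = "character",
  c2h2X1 = "integer", c2h2X2 = "integer",
  c2hcX1 = "integer", c2hcX2 = "integer",
  maxGap = "integer"
))

setValidity("WrkyPattern", function(object) {
  msg <- character()
  if (length(object@heptapeptides) < 1L)
    msg <- c(msg, "at least one heptapeptide pattern required")
  for (s in c("c2h2X1", "c2h2X2", "c2hcX1", "c2hcX2")) {
    r <- slot(object, s)
    if (length(r) != 2L || any(r < 0L) || r[1] > r[2])
      msg <- c(msg, paste0(s, " must be a non-empty 0-based range min<=max"))
  }
  if (length(object@maxGap) != 1L || object@maxGap < 0L)
    msg <- c(msg, "maxGap must be a single non-negative integer")
  if (length(msg)) msg else TRUE
})

#' Construct a WRKY domain search pattern
#'
#' @param heptapeptides heptapeptide alternatives as bracket patterns.  The
#'   default admits the common Q/K/E variants at position 6; pass
#'   \code{strict = TRUE} to keep only the canonical \code{WRKYGQK}.
#' @param strict logical; restrict to the invariant heptapeptide.
#' @param c2h2X1,c2h2X2 min/max spacer lengths of the C2H2 zinc finger.
#' @param c2hcX1,c2hcX2 min/max spacer lengths of the C2HC zinc finger.
#' @param maxGap maximum residues between heptapeptide and the first
#'   zinc-finger cysteine.
#' @return A [WrkyPattern-class] object.
#' @examples
#' wrkyPattern()
#' wrkyPattern(strict = TRUE)
#' @export
wrkyPattern <- function(heptapeptides = "WRKYG[QKE]K", strict = FALSE,
                        c2h2X1 = c(4L, 7L), c2h2X2 = c(22L, 23L),
                        c2hcX1 = c(4L, 8L), c2hcX2 = c(22L, 28L),
                        maxGap = 40L) {
  if (strict) heptapeptides <- "WRKYGQK"
  new("WrkyPattern", heptapeptides = heptapeptides,
      c2h2X1 = as.integer(c2h2X1), c2h2X2 = as.integer(c2h2X2),
      c2hcX1 = as.integer(c2hcX1), c2hcX2 = as.integer(c2hcX2),
      maxGap = as.integer(maxGap))
}

setMethod("show", "WrkyPattern", function(object) {
  cat("WrkyPattern\n")
  cat("  heptapeptide(s): ", paste(object@heptapeptides, collapse = " | "), "\n")
  cat(sprintf("  C2H2: C-X(%d-%d)-C-X(%d-%d)-H-X-H\n",
              object@c2h2X1[1], object@c2h2X1[2],
              object@c2h2X2[1], object@c2h2X2[2]))
  cat(sprintf("  C2HC: C-X(%d-%d)-C-X(%d-%d)-H-X-C\n",
              object@c2hcX1[1], object@c2hcX1[2],
              object@c2hcX2[1], object@c2hcX2[2]))
  cat("  max heptapeptide-to-finger gap:", object@maxGap, "residues\n")
})

#' Annotated genome bundle
#'
#' Container tying together the three inputs of a genome-wide survey: contig
#' sequences, transcript gene models, and the annotated proteome.  Gene
#' models are stored transcript-wise: a data.frame of identifiers plus
#' exon/CDS \linkS4class{GRangesList}s named by transcript.
#'
#' @slot contigs a \linkS4class{DNAStringSet} of contig/chromosome sequences.
#' @slot transcripts data.frame with columns \code{gene_id},
#'   \code{transcript_id}, \code{protein_id} (NA when non-coding),
#'   \code{seqid}, \code{strand}.
#' @slot exons,cds \linkS4class{GRangesList} keyed by \code{transcript_id};
#'   every transcript has >= 1 exon, CDS may be absent.
#' @slot proteome an \linkS4class{AAStringSet} keyed by \code{protein_id}.
#'
#' @seealso [genomeBundle()], [extractPromoter()], [buildCatalog()]
#' @exportClass GenomeBundle
setClass("GenomeBundle", representation(
  contigs = "DNAStringSet",
  transcripts = "data.frame",
  exons = "GRangesList",
  cds = "GRangesList",
  proteome = "AAStringSet"
))

setValidity("GenomeBundle", function(object) {
  msg <- character()
  tx <- object@transcripts
  need <- c("gene_id", "transcript_id", "protein_id", "seqid", "strand")
  if (!all(need %in% names(tx)))
    return(paste("transcripts must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(tx$transcript_id))
    msg <- c(msg, "duplicated transcript_id")
  bad <- setdiff(tx$seqid, names(object@contigs))
  if (length(bad))
    msg <- c(msg, paste("seqid(s) not in contigs:", paste(bad, collapse = ", ")))
  if (!all(tx$transcript_id %in% names(object@exons)))
    msg <- c(msg, "every transcript needs an exon set")
  withcds <- tx$transcript_id[tx$transcript_id %in% names(object@cds)]
  pid <- tx$protein_id[match(withcds, tx$transcript_id)]
  missing <- pid[!is.na(pid) & !(pid %in% names(object@proteome))]
  if (length(missing))
    msg <- c(msg, paste("protein_id(s) not in proteome:",
                        paste(unique(missing), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeBundle
#'
#' @param contigs \linkS4class{DNAStringSet} of genome sequences.
#' @param transcripts data.frame of transcript identifiers (see
#'   \linkS4class{GenomeBundle}).
#' @param exons,cds \linkS4class{GRangesList} named by transcript id.
#' @param proteome \linkS4class{AAStringSet} named by protein id.
#' @return A [GenomeBundle-class].
#' @export
genomeBundle <- function(contigs, transcripts, exons, cds, proteome) {
  new("GenomeBundle", contigs = contigs, transcripts = transcripts,
      exons = exons, cds = cds, proteome = proteome)
}

setMethod("show", "GenomeBundle", function(object) {
  cat("GenomeBundle\n")
  cat("  contigs:    ", length(object@contigs), "(",
      sum(as.numeric(Biostrings::width(object@contigs))), "bp )\n")
  cat("  genes:      ", length(unique(object@transcripts$gene_id)), "\n")
  cat("  transcripts:", nrow(object@transcripts), "\n")
  cat("  proteins:   ", length(object@proteome), "\n")
})

#' Curated WRKY family catalog
#'
#' One row per unique genomic locus whose representative protein carries at
#' least one complete WRKY domain (heptapeptide plus zinc finger).  Carries
#' the group I/II/III call, the phylogenetic subgroup for group II, and
#' curation flags.
#'
#' @slot entries data.frame with columns \code{protein_id}, \code{gene_id},
#'   \code{transcript_id}, \code{seqid}, \code{strand}, \code{locus_start},
#'   \code{locus_end}, \code{n_domains}, \code{zf_class}, \code{group},
#'   \code{subgroup}, \code{flags}.
#' @seealso [buildCatalog()], [assignSubgroups()], [writeCatalogTsv()]
#' @exportClass WrkyCatalog
setClass("WrkyCatalog", representation(entries = "data.frame"))

setValidity("WrkyCatalog", function(object) {
  e <- object@entries
  need <- c("protein_id", "gene_id", "transcript_id", "seqid", "strand",
            "locus_start", "locus_end", "n_domains", "zf_class", "group",
            "subgroup", "flags")
  if (!all(need %in% names(e)))
    return(paste("entries must have columns:", paste(need, collapse = ", ")))
  msg <- character()
  if (!all(e$group %in% c("I", "II", "III", "unclassified")))
    msg <- c(msg, "invalid group label")
  if (!all(e$subgroup %in% c("IIa", "IIb", "IIc", "IId", "IIe", "none")))
    msg <- c(msg, "invalid subgroup label")
  if (any(e$subgroup != "none" & e$group != "II"))
    msg <- c(msg, "subgroup may be set only for group II entries")
  ok1 <- e$group != "I" | e$n_domains >= 2
  ok2 <- e$group != "II" | (e$n_domains == 1 & e$zf_class == "C2H2")
  ok3 <- e$group != "III" | (e$n_domains == 1 & e$zf_class == "C2HC")
  if (!all(ok1 & ok2 & ok3))
    msg <- c(msg, "group labels inconsistent with domain evidence")
  if (length(msg)) msg else TRUE
})

setMethod("show", "WrkyCatalog", function(object) {
  e <- object@entries
  cat("WrkyCatalog with", nrow(e), "entries\n")
  if (nrow(e)) {
    tb <- table(factor(e$group, levels = c("I", "II", "III", "unclassified")))
    cat("  groups:  ", paste(sprintf("%s=%d", names(tb), tb), collapse = "  "), "\n")
    if (any(e$subgroup != "none")) {
      sb <- table(e$subgroup[e$subgroup != "none"])
      cat("  subgroups:", paste(sprintf("%s=%d", names(sb), sb), collapse = "  "), "\n")
    }
  }
})

#' Accessor: catalog entries as a data.frame
#' @param x a [WrkyCatalog-class]
#' @return data.frame of catalog rows.
#' @export
catalogEntries <- function(x) {
  stopifnot(is(x, "WrkyCatalog"))
  x@entries
}

#' Accessor: family group counts
#' @param x a [WrkyCatalog-class]
#' @return named integer vector over groups I, II, III, unclassified.
#' @export
groupCounts <- function(x) {
  stopifnot(is(x, "WrkyCatalog"))
  tb <- table(factor(x@entries$group, levels = c("I", "II", "III", "unclassified")))
  stats::setNames(as.integer(tb), names(tb))
}

#' Promoter cis-element count report
#'
#' Per-gene counts of cis-regulatory element matches in promoter sequences,
#' one column per motif class, with a totals vector equal to the column sums.
#'
#' @slot counts integer matrix, genes x motifs.
#' @slot totals named integer vector of column sums.
#' @seealso [countTable()], [scanPromoter()]
#' @exportClass PromoterReport
setClass("PromoterReport", representation(counts = "matrix", totals = "integer"))

setValidity("PromoterReport", function(object) {
  if (!identical(unname(colSums(object@counts)), as.numeric(object@totals)))
    return("totals must equal column sums")
  if (!identical(names(object@totals), colnames(object@counts)))
    return("totals names must match count columns")
  TRUE
})

setMethod("show", "PromoterReport", function(object) {
  cat("PromoterReport:", nrow(object@counts), "promoters x",
      ncol(object@counts), "motif classes\n")
  print(utils::head(object@counts, 10))
  if (nrow(object@counts) > 10) cat("  ...\n")
  cat("totals:\n")
  print(object@totals)
})

#' Accessor: promoter count matrix
#' @param x a [PromoterReport-class]
#' @return integer matrix of per-gene counts.
#' @export
reportCounts <- function(x) {
  stopifnot(is(x, "PromoterReport"))
  x@counts
}

#' Accessor: promoter report column totals
#' @param x a [PromoterReport-class]
#' @return named integer vector.
#' @export
reportTotals <- function(x) {
  stopifnot(is(x, "PromoterReport"))
  x@totals
}

#' Discovered ungapped motif model
#'
#' A position weight matrix with its ZOOPS site assignments (at most one site
#' per input record), the per-column information content, and the consensus.
#'
#' @slot pwm numeric matrix, alphabet x width; columns sum to 1.
#' @slot sites data.frame with columns \code{record}, \code{offset} (1-based
#'   start in the record), \code{site} (matched text).
#' @slot ic total information content in bits.
#' @slot consensus majority-letter consensus string.
#' @seealso [discoverMotifs()]
#' @exportClass MotifModel
setClass("MotifModel", representation(
  pwm = "matrix", sites = "data.frame", ic = "numeric", consensus = "character"
))

setValidity("MotifModel", function(object) {
  if (any(abs(colSums(object@pwm) - 1) > 1e-9))
    return("every PWM column must sum to 1")
  if (anyDuplicated(object@sites$record))
    return("at most one site per record (ZOOPS)")
  TRUE
})

setMethod("show", "MotifModel", function(object) {
  cat(sprintf("MotifModel  width=%d  sites=%d  IC=%.2f bits\n",
              ncol(object@pwm), nrow(object@sites), object@ic))
  cat("  consensus:", object@consensus, "\n")
})

#' Accessor: motif consensus string
#' @param x a [MotifModel-class]
#' @return character scalar.
#' @export
motifConsensus <- function(x) {
  stopifnot(is(x, "MotifModel"))
  x@consensus
}

#' Accessor: motif position weight matrix
#' @param x a [MotifModel-class]
#' @return numeric matrix (alphabet x width).
#' @export
motifPwm <- function(x) {
  stopifnot(is(x, "MotifModel"))
  x@pwm
}

#' Accessor: ZOOPS site assignments
#' @param x a [MotifModel-class]
#' @return data.frame of sites (record, offset, site).
#' @export
motifSites <- function(x) {
  stopifnot(is(x, "MotifModel"))
  x@sites
}
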