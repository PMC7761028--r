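#' Built-in cis-regulatory element patterns
#'
#' The six element classes scanned in group-IIa WRKY promoters, as IUPAC
#' degenerate DNA strings (alternatives OR-ed): the WRKY binding W-box
#' (\code{YTGACY}, i.e. (C/T)TGAC(C/T)); the G-box (\code{CACGTG}); the
#' GCC-box (\code{GCCGCC}); the salicylic-acid-responsive TCA-element
#' (\code{CCATCTTTTT}, \code{TCAGAAGAGG}); the jasmonate-responsive MeJa-RE
#' (\code{CGTCA}); and the ethylene-responsive ERE (\code{ATTTCAAA},
#' \code{ATTTCATA}).
#'
#' @return named list of character vectors of IUPAC patterns, in report
#'   column order.
#' @examples
#' names(builtinMotifs())
#' @export
builtinMotifs <- function() {
  list(
    "W-box" = "YTGACY",
    "G-box" = "CACGTG",
    "GCC-box" = "GCCGCC",
    "TCA-element" = c("CCATCTTTTT", "TCAGAAGAGG"),
    "MeJa-RE" = "CGTCA",
    "ERE" = c("ATTTCAAA", "ATTTCATA")
  )
}

as_dna_string <- function(seq) {
  if (is(seq, "AAString") || is(seq, "AAStringSet"))
    stop("protein input; DNA sequence required")
  if (is(seq, "DNAStringSet")) {
    stopifnot(length(seq) == 1L)
    return(seq[[1L]])
  }
  if (is(seq, "DNAString")) return(seq)
  Biostrings::DNAString(seq)
}

empty_hits <- function() {
  data.frame(motif = character(), strand = character(), start = integer(),
             end = integer(), offset = integer(), match = character(),
             stringsAsFactors = FALSE)
}

match_one <- function(subject, pattern) {
  m <- Biostrings::matchPattern(pattern, subject, fixed = FALSE)
  if (!length(m)) return(NULL)
  data.frame(start = BiocGenerics::start(m), end = BiocGenerics::end(m),
             match = as.character(m), stringsAsFactors = FALSE)
}

#' Scan a promoter for cis-regulatory elements
#'
#' Reports every match (overlapping matches included) of each motif pattern.
#' The promoter's 3' end is taken to abut the ATG, so a hit starting at
#' sequence position \code{i} in a promoter of length L gets ATG-relative
#' offset \code{i - L - 1} (offset -1 = base immediately upstream of the
#' ATG).  In \code{strandMode = "both"} the reverse strand is scanned too
#' (coordinates reported on the forward strand); a reverse-strand match of a
#' self-reverse-complementary pattern over the same interval as a forward
#' match is suppressed so palindromes count once.
#'
#' @param seq promoter DNA (character, \linkS4class{DNAString}, or
#'   single-record \linkS4class{DNAStringSet}); 3' end at the ATG.
#' @param motifs named list of IUPAC pattern vectors; default
#'   [builtinMotifs()].
#' @param strandMode \code{"forward"} (default) or \code{"both"}.
#' @return data.frame with columns \code{motif}, \code{strand},
#'   \code{start}, \code{end} (1-based in the promoter), \code{offset}
#'   (ATG-relative start), \code{match}.
#' @examples
#' scanPromoter("TTGACTTTGACT")[, c("motif", "offset")]
#' @export
scanPromoter <- function(seq, motifs = builtinMotifs(),
                         strandMode = c("forward", "both")) {
  strandMode <- match.arg(strandMode)
  subject <- as_dna_string(seq)
  L <- length(subject)
  rows <- list()
  for (nm in names(motifs)) {
    for (pat in motifs[[nm]]) {
      fw <- match_one(subject, pat)
      if (!is.null(fw)) {
        fw$motif <- nm; fw$strand <- "+"
        rows[[length(rows) + 1L]] <- fw
      }
      if (strandMode == "both") {
        rcpat <- as.character(
          Biostrings::reverseComplement(Biostrings::DNAString(pat)))
        rv <- match_one(subject, rcpat)
        if (!is.null(rv)) {
          rv$motif <- nm; rv$strand <- "-"
          rows[[length(rows) + 1L]] <- rv
        }
      }
    }
  }
  if (!length(rows)) return(empty_hits())
  hits <- do.call(rbind, rows)
  if (strandMode == "both") {
    # palindromic patterns produce a forward and a reverse hit over the same
    # interval; count the interval once
    key <- paste(hits$motif, hits$start, hits$end)
    hits <- hits[order(key, hits$strand), ]
    hits <- hits[!duplicated(paste(hits$motif, hits$start, hits$end)), ]
  }
  hits$offset <- hits$start - L - 1L
  hits <- hits[order(hits$motif, hits$start, hits$strand),
               c("motif", "strand", "start", "end", "offset", "match")]
  rownames(hits) <- NULL
  hits
}

#' Find the bipartite double W-box
#'
#' Two adjacent full W-boxes whose TGAC cores are spaced by exactly two
#' nucleotides, i.e. the 12-mer \code{YTGACYYTGACY}.  The reported offset is
#' the ATG-relative start of the first W-box.
#'
#' @param seq promoter DNA (3' end at the ATG).
#' @return data.frame as in [scanPromoter()] with motif
#'   \code{"double-W-box"}.
#' @examples
#' prom <- paste0(strrep("A", 2200), "TTGACTTTGACT", strrep("A", 788))
#' findBipartiteWbox(prom)$offset  # -800
#' @export
findBipartiteWbox <- function(seq) {
  subject <- as_dna_string(seq)
  L <- length(subject)
  m <- match_one(subject, "YTGACYYTGACY")
  if (is.null(m)) return(empty_hits())
  data.frame(motif = "double-W-box", strand = "+", start = m$start,
             end = m$end, offset = m$start - L - 1L, match = m$match,
             stringsAsFactors = FALSE)
}

#' Per-gene cis-element count table
#'
#' One row per promoter in input order, one column per motif class, plus a
#' totals vector equal to the column sums (the layout of a promoter survey
#' table).
#'
#' @param promoters named \linkS4class{DNAStringSet} (or named character
#'   vector / list) of promoter sequences.
#' @param motifs named list of IUPAC pattern vectors.
#' @param strandMode passed to [scanPromoter()].
#' @return A [PromoterReport-class].
#' @export
countTable <- function(promoters, motifs = builtinMotifs(),
                       strandMode = "forward") {
  if (!length(promoters)) stop("no promoters supplied")
  nms <- names(promoters)
  if (is.null(nms)) nms <- paste0("promoter", seq_along(promoters))
  counts <- t(vapply(seq_along(promoters), function(i) {
    h <- scanPromoter(promoters[[i]], motifs, strandMode)
    vapply(names(motifs), function(nm) sum(h$motif == nm), integer(1))
  }, integer(length(motifs))))
  dimnames(counts) <- list(nms, names(motifs))
  promoterReport(counts)
}

#' Construct a PromoterReport from a count matrix
#'
#' Useful for re-totaling externally produced per-gene counts with the same
#' machinery that backs [countTable()].
#'
#' @param counts integer matrix, genes x motif classes.
#' @return A [PromoterReport-class] with totals = column sums.
#' @export
promoterReport <- function(counts) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  new("PromoterReport", counts = counts,
      totals = stats::setNames(as.integer(colSums(counts)), colnames(counts)))
}

#' Write a promoter report as TSV
#'
#' @param report a [PromoterReport-class].
#' @param path output path; columns: seq, one per motif; final row
#'   \code{total}.
#' @return \code{path}, invisibly.
#' @export
writeReportTsv <- function(report, path) {
  stopifnot(is(report, "PromoterReport"))
  df <- data.frame(seq = rownames(report@counts), report@counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  df <- rbind(df, c(seq = "total", as.list(report@totals)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
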