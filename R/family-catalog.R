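#' Collapse transcript redundancy to unique genomic loci
#'
#' Transcripts are clustered by single-linkage CDS overlap (>= 1 bp, same
#' contig and strand), so alternative isoforms annotated over one genomic
#' locus collapse to a single cluster.  The cluster representative is the
#' transcript with the longest encoded protein; ties break to the
#' lexicographically smallest protein id.
#'
#' @param bundle a [GenomeBundle-class].
#' @return data.frame with one row per CDS-bearing transcript: columns
#'   \code{cluster} (integer id), \code{transcript_id}, \code{gene_id},
#'   \code{protein_id}, \code{seqid}, \code{strand}, \code{representative}
#'   (logical).
#' @export
dedupeByLocus <- function(bundle) {
  stopifnot(is(bundle, "GenomeBundle"))
  tx <- bundle@transcripts
  coding <- tx[tx$transcript_id %in% names(bundle@cds) & !is.na(tx$protein_id), ,
               drop = FALSE]
  if (!nrow(coding)) stop("no CDS-bearing transcripts in bundle")
  cds <- bundle@cds[coding$transcript_id]
  gr <- unlist(cds, use.names = FALSE)
  gr$tx <- rep(seq_len(nrow(coding)), lengths(cds))
  ov <- GenomicRanges::findOverlaps(gr, gr, minoverlap = 1L,
                                    ignore.strand = FALSE)
  a <- gr$tx[S4Vectors::queryHits(ov)]
  b <- gr$tx[S4Vectors::subjectHits(ov)]
  # union-find single linkage over transcripts
  parent <- seq_len(nrow(coding))
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_along(a)) {
    ra <- find(a[k]); rb <- find(b[k])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  comp <- vapply(seq_len(nrow(coding)), find, integer(1))
  cluster <- match(comp, sort(unique(comp)))
  plen <- Biostrings::width(bundle@proteome)[match(coding$protein_id,
                                                   names(bundle@proteome))]
  rep_flag <- logical(nrow(coding))
  for (cl in unique(cluster)) {
    idx <- which(cluster == cl)
    best <- idx[order(-plen[idx], coding$protein_id[idx])][1L]
    rep_flag[best] <- TRUE
  }
  data.frame(cluster = cluster,
             transcript_id = coding$transcript_id,
             gene_id = coding$gene_id,
             protein_id = coding$protein_id,
             seqid = coding$seqid,
             strand = coding$strand,
             representative = rep_flag,
             stringsAsFactors = FALSE)[order(cluster), ]
}

#' Build the curated WRKY family catalog
#'
#' Runs the identification funnel: collapse transcripts to unique loci, scan
#' each locus representative for WRKY domains, keep loci whose representative
#' carries at least one complete domain (heptapeptide plus zinc finger), and
#' classify: two or more complete domains puts an entry in group I; a single
#' domain is group II with a C2H2 finger and group III with a C2HC finger.
#'
#' @param bundle a [GenomeBundle-class].
#' @param pattern a [WrkyPattern-class].
#' @param keepPartial keep loci whose representative has a heptapeptide but
#'   no zinc finger, flagged \code{partial_domain}.
#' @return A [WrkyCatalog-class]; subgroups are \code{"none"} until
#'   [assignSubgroups()] is applied.
#' @export
buildCatalog <- function(bundle, pattern = wrkyPattern(), keepPartial = FALSE) {
  stopifnot(is(bundle, "GenomeBundle"))
  if (!length(bundle@proteome)) stop("empty proteome")
  clusters <- dedupeByLocus(bundle)
  reps <- clusters[clusters$representative, , drop = FALSE]
  rows <- lapply(seq_len(nrow(reps)), function(i) {
    r <- reps[i, ]
    hits <- findWrkyDomains(as.character(bundle@proteome[[r$protein_id]]),
                            pattern)
    ncomplete <- sum(hits$complete)
    if (nrow(hits) == 0L) return(NULL)
    if (ncomplete == 0L && !keepPartial) return(NULL)
    first <- if (ncomplete) hits[hits$complete, ][1L, ] else NULL
    zf <- if (ncomplete) first$zf_class else "none"
    group <- if (ncomplete >= 2L) "I"
             else if (ncomplete == 1L && zf == "C2H2") "II"
             else if (ncomplete == 1L && zf == "C2HC") "III"
             else "unclassified"
    cdsr <- range(unlist(bundle@cds[
      clusters$transcript_id[clusters$cluster == r$cluster]],
      use.names = FALSE))
    data.frame(protein_id = r$protein_id, gene_id = r$gene_id,
               transcript_id = r$transcript_id, seqid = r$seqid,
               strand = r$strand,
               locus_start = GenomicRanges::start(cdsr)[1L],
               locus_end = GenomicRanges::end(cdsr)[1L],
               n_domains = ncomplete, zf_class = zf, group = group,
               subgroup = "none",
               flags = if (ncomplete == 0L) "partial_domain" else "",
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  entries <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein_id = character(), gene_id = character(),
               transcript_id = character(), seqid = character(),
               strand = character(), locus_start = integer(),
               locus_end = integer(), n_domains = integer(),
               zf_class = character(), group = character(),
               subgroup = character(), flags = character(),
               stringsAsFactors = FALSE)
  rownames(entries) <- NULL
  new("WrkyCatalog", entries = entries)
}

# longest exact common substring length (small inputs; suffix-free DP)
lcs_substring <- function(a, b) {
  ca <- strsplit(a, "")[[1L]]; cb <- strsplit(b, "")[[1L]]
  if (!length(ca) || !length(cb)) return(0L)
  prev <- integer(length(cb)); best <- 0L
  for (i in seq_along(ca)) {
    cur <- integer(length(cb))
    match_i <- ca[i] == cb
    cur[match_i] <- c(0L, prev)[which(match_i)] + 1L
    best <- max(best, cur)
    prev <- cur
  }
  best
}

#' Assign phylogenetic subgroups to group-II catalog entries
#'
#' Each group-II entry receives the subgroup label (IIa-IIe) of its nearest
#' labeled reference leaf by patristic (tree path) distance.  Ties are broken
#' toward the reference sharing the longest exact common substring with the
#' query protein when sequences are supplied, falling back to the
#' lexicographically smallest reference id.
#'
#' @param catalog a [WrkyCatalog-class].
#' @param tree an \code{ape} \code{phylo} containing every group-II entry
#'   (tips named by protein id) and the reference proteins.
#' @param referenceSubgroups named character vector mapping reference tip
#'   labels to subgroups \code{"IIa".."IIe"}; every subgroup must be
#'   represented.
#' @param sequences optional \linkS4class{AAStringSet} covering queries and
#'   references, used only for tie-breaking.
#' @return The catalog with \code{subgroup} filled in for group-II entries.
#' @export
assignSubgroups <- function(catalog, tree, referenceSubgroups,
                            sequences = NULL) {
  stopifnot(is(catalog, "WrkyCatalog"), inherits(tree, "phylo"))
  wanted <- c("IIa", "IIb", "IIc", "IId", "IIe")
  missing <- setdiff(wanted, unique(referenceSubgroups))
  if (length(missing))
    stop("no reference for subgroup(s): ", paste(missing, collapse = ", "))
  e <- catalog@entries
  q <- e$protein_id[e$group == "II"]
  absent <- setdiff(q, tree$tip.label)
  if (length(absent))
    stop("group-II entries missing from tree: ", paste(absent, collapse = ", "))
  refs <- intersect(names(referenceSubgroups), tree$tip.label)
  if (!length(refs)) stop("no reference tips in tree")
  D <- ape::cophenetic.phylo(tree)
  for (id in q) {
    d <- D[id, refs]
    best <- refs[abs(d - min(d)) < 1e-12]
    if (length(best) > 1L && !is.null(sequences) &&
        id %in% names(sequences)) {
      avail <- best[best %in% names(sequences)]
      if (length(avail)) {
        l <- vapply(avail, function(r)
          lcs_substring(as.character(sequences[[id]]),
                        as.character(sequences[[r]])), integer(1))
        best <- avail[order(-l, avail)]
      } else best <- sort(best)
    } else best <- sort(best)
    e$subgroup[e$protein_id == id] <- unname(referenceSubgroups[best[1L]])
  }
  new("WrkyCatalog", entries = e)
}
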