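#' Read a FASTA file
#'
#' Thin wrapper around Biostrings readers that normalizes record ids to the
#' first whitespace-delimited token of the header and keeps the remainder as
#' a description in \code{mcols()}.
#'
#' @param path path to a FASTA file.
#' @param alphabet \code{"dna"} or \code{"protein"}.
#' @return A \linkS4class{DNAStringSet} or \linkS4class{AAStringSet}, in file
#'   order, named by record id.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">a some gene", "ACGT"), tf)
#' readFasta(tf, "dna")
#' @export
readFasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  x <- if (alphabet == "dna") Biostrings::readDNAStringSet(path)
       else Biostrings::readAAStringSet(path)
  hdr <- names(x)
  if (length(x)) {
    ids <- sub("\\s.*$", "", hdr)
    desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
    names(x) <- ids
    S4Vectors::mcols(x)$description <- desc
  }
  x
}

#' Write sequences as FASTA
#'
#' @param x an \linkS4class{XStringSet} (or named character vector).
#' @param path output file; lines wrapped at 60 columns.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/exon/CDS features, resolving parentage through ID/Parent
#' attributes, into the transcript-wise representation used by
#' \linkS4class{GenomeBundle}: one entry per mRNA with its exon and CDS
#' ranges.  Coordinates stay in the 1-based closed GFF3/Bioconductor frame.
#'
#' @param path path to a GFF3 file.
#' @return list with elements \code{transcripts} (data.frame: gene_id,
#'   transcript_id, protein_id, seqid, strand), \code{exons} and \code{cds}
#'   (\linkS4class{GRangesList} named by transcript id).
#' @export
readGff3 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  g <- rtracklayer::import(path, format = "gff3")
  type <- as.character(g$type)
  ids <- as.character(g$ID)
  parents <- g$Parent  # CharacterList
  firstParent <- function(i) {
    p <- parents[[i]]
    if (length(p) == 0L) NA_character_ else as.character(p[1])
  }
  mrna <- which(type %in% c("mRNA", "transcript"))
  if (!length(mrna)) stop("no mRNA/transcript features in ", path)
  txid <- ids[mrna]
  if (anyNA(txid)) stop("mRNA feature without ID attribute")
  strand_chr <- as.character(GenomicRanges::strand(g))
  if (any(strand_chr[mrna] == "*"))
    stop("unknown strand on mRNA ", paste(txid[strand_chr[mrna] == "*"],
                                          collapse = ", "))
  pid <- if (!is.null(g$protein_id)) as.character(g$protein_id)
         else rep(NA_character_, length(g))
  tx <- data.frame(
    gene_id = vapply(mrna, firstParent, character(1)),
    transcript_id = txid,
    protein_id = pid[mrna],
    seqid = as.character(GenomicRanges::seqnames(g))[mrna],
    strand = strand_chr[mrna],
    stringsAsFactors = FALSE
  )
  tx$gene_id[is.na(tx$gene_id)] <- tx$transcript_id[is.na(tx$gene_id)]

  pickChildren <- function(what) {
    idx <- which(type == what)
    if (!length(idx)) {
      gl <- GenomicRanges::GRangesList()
      return(gl)
    }
    par <- vapply(idx, firstParent, character(1))
    if (anyNA(par)) stop(what, " feature without Parent attribute")
    unknown <- setdiff(par, txid)
    if (length(unknown))
      stop(what, " with unresolved mRNA parent: ",
           paste(unknown, collapse = ", "))
    gr <- g[idx]
    S4Vectors::mcols(gr) <- NULL
    spl <- GenomicRanges::split(gr, factor(par, levels = unique(par)))
    # sort ranges ascending within each transcript
    spl <- GenomicRanges::GRangesList(lapply(spl, GenomicRanges::sort))
    spl
  }
  exons <- pickChildren("exon")
  cds <- pickChildren("CDS")
  # CDS protein_id may live on CDS lines rather than the mRNA
  cdsIdx <- which(type == "CDS")
  if (length(cdsIdx) && anyNA(tx$protein_id)) {
    par <- vapply(cdsIdx, firstParent, character(1))
    m <- match(tx$transcript_id, par)
    fill <- is.na(tx$protein_id) & !is.na(m)
    tx$protein_id[fill] <- pid[cdsIdx][m[fill]]
  }
  missingExon <- setdiff(tx$transcript_id, names(exons))
  if (length(missingExon))
    stop("transcript without exons: ", paste(missingExon, collapse = ", "))
  list(transcripts = tx, exons = exons[tx$transcript_id],
       cds = cds[intersect(tx$transcript_id, names(cds))])
}

#' Assemble a GenomeBundle from files
#'
#' @param genomeFasta path to the genome FASTA.
#' @param gff3 path to the GFF3 annotation.
#' @param proteomeFasta path to the proteome FASTA.
#' @return A [GenomeBundle-class].
#' @export
readGenomeBundle <- function(genomeFasta, gff3, proteomeFasta) {
  contigs <- readFasta(genomeFasta, "dna")
  ann <- readGff3(gff3)
  proteome <- readFasta(proteomeFasta, "protein")
  genomeBundle(contigs, ann$transcripts, ann$exons, ann$cds, proteome)
}

#' Extract the promoter upstream of a transcript's ATG
#'
#' Returns up to \code{length} bases immediately 5' of the first CDS base on
#' the coding strand (reverse-complemented for minus-strand genes), so that
#' the last base of the result sits at position -1 relative to the A of the
#' ATG.  Promoters running off the contig edge are truncated with a warning
#' rather than dropped.
#'
#' @param bundle a [GenomeBundle-class].
#' @param transcriptId transcript whose CDS anchors the promoter.
#' @param length promoter length in bp (default 3000, the conventional
#'   upstream regulatory window).
#' @return A \linkS4class{DNAStringSet} of one record named
#'   \code{<transcriptId>_promoter}.
#' @export
extractPromoter <- function(bundle, transcriptId, length = 3000L) {
  stopifnot(is(bundle, "GenomeBundle"))
  if (!transcriptId %in% names(bundle@cds))
    stop("transcript has no CDS: ", transcriptId)
  cds <- bundle@cds[[transcriptId]]
  tx <- bundle@transcripts
  row <- tx[tx$transcript_id == transcriptId, , drop = FALSE]
  contig <- bundle@contigs[[row$seqid]]
  clen <- length(contig)
  if (row$strand == "+") {
    atg <- min(GenomicRanges::start(cds))
    from <- atg - length
    if (from < 1L) {
      warning("promoter of ", transcriptId, " truncated at contig start (",
              atg - 1L, " bp available)")
      from <- 1L
    }
    if (atg == 1L) stop("no upstream sequence for ", transcriptId)
    prom <- Biostrings::subseq(contig, from, atg - 1L)
  } else {
    atg <- max(GenomicRanges::end(cds))
    to <- atg + length
    if (to > clen) {
      warning("promoter of ", transcriptId, " truncated at contig end (",
              clen - atg, " bp available)")
      to <- clen
    }
    if (atg == clen) stop("no upstream sequence for ", transcriptId)
    prom <- Biostrings::reverseComplement(
      Biostrings::subseq(contig, atg + 1L, to))
  }
  out <- Biostrings::DNAStringSet(prom)
  names(out) <- paste0(transcriptId, "_promoter")
  out
}

#' Write a phylogenetic tree as Newick
#'
#' Branch lengths are kept; integer bootstrap supports (if present in
#' \code{tree$node.label}) become internal node labels.
#'
#' @param tree an \code{ape} \code{phylo} object.
#' @param path output file, or \code{NULL} to return the Newick string.
#' @return The Newick text (invisibly when written to a file).
#' @export
writeNewick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a Newick tree
#' @param path file path or a Newick string.
#' @return an \code{ape} \code{phylo} object.
#' @export
readNewick <- function(path) {
  if (file.exists(path)) ape::read.tree(path) else ape::read.tree(text = path)
}

#' Write a WRKY catalog as TSV
#'
#' Fixed column order: protein_id, gene_id, transcript_id, seqid, strand,
#' locus_start, locus_end, n_domains, zf_class, group, subgroup, flags.  An
#' empty catalog yields a header-only file.
#'
#' @param catalog a [WrkyCatalog-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCatalogTsv <- function(catalog, path) {
  stopifnot(is(catalog, "WrkyCatalog"))
  cols <- c("protein_id", "gene_id", "transcript_id", "seqid", "strand",
            "locus_start", "locus_end", "n_domains", "zf_class", "group",
            "subgroup", "flags")
  utils::write.table(catalog@entries[, cols, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export promoter hits as BED-like TSV
#'
#' Columns: gene, start, end (0-based half-open, BED convention), motif,
#' strand, match, offset (ATG-relative start, -1 = base before ATG).
#'
#' @param hits data.frame of hits from [scanPromoter()] /
#'   [findBipartiteWbox()] with a \code{gene} column.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeHitsBed <- function(hits, path) {
  bed <- data.frame(
    gene = hits$gene,
    start = hits$start - 1L,
    end = hits$end,
    motif = hits$motif,
    strand = hits$strand,
    match = hits$match,
    offset = hits$offset,
    stringsAsFactors = FALSE
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
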