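#' Write a GenomeBundle's gene models as GFF3
#'
#' Emits gene/mRNA/exon/CDS features with ID/Parent attributes (and
#' \code{protein_id} on mRNA lines), 1-based inclusive coordinates.
#'
#' @param bundle a [GenomeBundle-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeBundleGff3 <- function(bundle, path) {
  stopifnot(is(bundle, "GenomeBundle"))
  tx <- bundle@transcripts
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  fmt <- function(seqid, type, start, end, strand, attrs)
    sprintf("%s\twrkymine\t%s\t%d\t%d\t.\t%s\t.\t%s",
            seqid, type, start, end, strand, attrs)
  for (g in unique(tx$gene_id)) {
    sub <- tx[tx$gene_id == g, , drop = FALSE]
    allEx <- unlist(bundle@exons[sub$transcript_id], use.names = FALSE)
    writeLines(fmt(sub$seqid[1L], "gene",
                   min(GenomicRanges::start(allEx)),
                   max(GenomicRanges::end(allEx)),
                   sub$strand[1L], paste0("ID=", g)), con)
    for (i in seq_len(nrow(sub))) {
      tid <- sub$transcript_id[i]
      ex <- bundle@exons[[tid]]
      attrs <- paste0("ID=", tid, ";Parent=", g)
      if (!is.na(sub$protein_id[i]))
        attrs <- paste0(attrs, ";protein_id=", sub$protein_id[i])
      writeLines(fmt(sub$seqid[i], "mRNA",
                     min(GenomicRanges::start(ex)),
                     max(GenomicRanges::end(ex)), sub$strand[i], attrs), con)
      for (j in seq_along(ex))
        writeLines(fmt(sub$seqid[i], "exon", GenomicRanges::start(ex)[j],
                       GenomicRanges::end(ex)[j], sub$strand[i],
                       paste0("ID=", tid, ".exon", j, ";Parent=", tid)), con)
      if (tid %in% names(bundle@cds)) {
        cd <- bundle@cds[[tid]]
        for (j in seq_along(cd))
          writeLines(fmt(sub$seqid[i], "CDS", GenomicRanges::start(cd)[j],
                         GenomicRanges::end(cd)[j], sub$strand[i],
                         paste0("ID=", tid, ".cds", j, ";Parent=", tid)), con)
      }
    }
  }
  invisible(path)
}

#' Run the WRKY identification funnel
#'
#' Orchestrates dedupe -> domain scan -> classification and logs the count
#' at each filtering step (annotated transcripts, unique loci,
#' domain-bearing loci) via \code{message()}.
#'
#' @param bundle a [GenomeBundle-class], or a list/vector of three paths
#'   \code{c(genome, gff3, proteome)}.
#' @param pattern a [WrkyPattern-class].
#' @param keepPartial see [buildCatalog()].
#' @param out optional path for the catalog TSV.
#' @return A [WrkyCatalog-class], invisibly when \code{out} is given.
#' @export
runIdentify <- function(bundle, pattern = wrkyPattern(), keepPartial = FALSE,
                        out = NULL) {
  if (!is(bundle, "GenomeBundle")) {
    stopifnot(length(bundle) == 3L)
    bundle <- readGenomeBundle(bundle[[1L]], bundle[[2L]], bundle[[3L]])
  }
  if (!length(bundle@proteome)) stop("empty proteome")
  clusters <- dedupeByLocus(bundle)
  catalog <- buildCatalog(bundle, pattern, keepPartial)
  message("identify funnel: ", nrow(clusters), " annotated transcripts -> ",
          max(clusters$cluster), " unique loci -> ",
          nrow(catalogEntries(catalog)), " WRKY-domain loci")
  if (!is.null(out)) {
    writeCatalogTsv(catalog, out)
    return(invisible(catalog))
  }
  catalog
}

#' Build a bootstrapped NJ tree from protein sequences
#'
#' Aligns (unless already aligned), computes p-distances and runs
#' neighbor joining with bootstrap supports.
#'
#' @param proteins \linkS4class{AAStringSet} or FASTA path.
#' @param bootstrap number of bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param aligned set TRUE when the input is already an alignment.
#' @param out optional Newick output path.
#' @return an \code{ape} \code{phylo} with supports.
#' @export
runTree <- function(proteins, bootstrap = 1000L, seed = 1L, aligned = FALSE,
                    out = NULL) {
  if (is.character(proteins) && length(proteins) == 1L &&
      file.exists(proteins))
    proteins <- readFasta(proteins, "protein")
  aln <- if (aligned) proteins else progressiveMsa(proteins)
  tree <- bootstrapTree(aln, n = bootstrap, seed = seed)
  if (!is.null(out)) writeNewick(tree, out)
  tree
}

#' Scan promoters and emit the element count report
#'
#' @param promoters \linkS4class{DNAStringSet} or FASTA path.
#' @param motifs named list of IUPAC patterns (default [builtinMotifs()]).
#' @param strandMode \code{"forward"} or \code{"both"}.
#' @param out optional TSV output path for the count table.
#' @return list with \code{report} ([PromoterReport-class]), \code{hits}
#'   (per-gene hit data.frame), and \code{bipartite} (double W-box hits).
#' @export
runPromoters <- function(promoters, motifs = builtinMotifs(),
                         strandMode = "forward", out = NULL) {
  if (is.character(promoters) && length(promoters) == 1L &&
      file.exists(promoters))
    promoters <- readFasta(promoters, "dna")
  report <- countTable(promoters, motifs, strandMode)
  hits <- do.call(rbind, lapply(names(promoters), function(g) {
    h <- scanPromoter(promoters[[g]], motifs, strandMode)
    if (nrow(h)) cbind(gene = g, h, stringsAsFactors = FALSE) else NULL
  }))
  bip <- do.call(rbind, lapply(names(promoters), function(g) {
    h <- findBipartiteWbox(promoters[[g]])
    if (nrow(h)) cbind(gene = g, h, stringsAsFactors = FALSE) else NULL
  }))
  if (!is.null(out)) writeReportTsv(report, out)
  list(report = report, hits = hits, bipartite = bip)
}

#' Discover conserved motifs in a sequence set
#'
#' @param records sequences (\linkS4class{XStringSet} or FASTA path plus
#'   \code{alphabet}).
#' @param nmotifs,wmin,wmax,seed see [discoverMotifs()].
#' @param alphabet used when reading from file.
#' @param out optional MEME-format output path.
#' @return list of [MotifModel-class].
#' @export
runMotifs <- function(records, nmotifs = 6L, wmin = 6L, wmax = 50L,
                      seed = 1L, alphabet = "protein", out = NULL) {
  if (is.character(records) && length(records) == 1L && file.exists(records))
    records <- readFasta(records, alphabet)
  models <- discoverMotifs(records, nmotifs, wmin, wmax, seed)
  if (!is.null(out) && length(models)) writeMemeText(models, out)
  models
}

#' Physico-chemical properties of a protein set
#'
#' @param proteins \linkS4class{AAStringSet} or FASTA path.
#' @param out optional TSV output path.
#' @return data.frame (id, length, mw, pi).
#' @export
runProps <- function(proteins, out = NULL) {
  if (is.character(proteins) && length(proteins) == 1L &&
      file.exists(proteins))
    proteins <- readFasta(proteins, "protein")
  props <- proteinProperties(proteins)
  if (!is.null(out))
    utils::write.table(props, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  props
}

#' Relative-expression analysis of a Ct table
#'
#' Runs [deltaDeltaCt()] then, per timepoint, [anovaTukey()] on the
#' replicate folds across conditions, attaching compact letters.
#'
#' @param ct data.frame or CSV/TSV path with the Ct table columns.
#' @param targetGene,referenceGene,calibratorCondition see
#'   [deltaDeltaCt()].
#' @param alpha significance level for Tukey letters.
#' @param out optional TSV output path.
#' @return data.frame of fold changes with a \code{letter} column.
#' @export
runQpcr <- function(ct, targetGene = "target", referenceGene = "reference",
                    calibratorCondition = "control", alpha = 0.05,
                    out = NULL) {
  if (is.character(ct) && length(ct) == 1L && file.exists(ct))
    ct <- utils::read.delim(ct, sep = if (grepl("\\.csv$", ct)) "," else "\t",
                            stringsAsFactors = FALSE)
  fc <- deltaDeltaCt(ct, targetGene, referenceGene, calibratorCondition)
  fc$letter <- NA_character_
  for (tp in unique(fc$timepoint)) {
    idx <- which(fc$timepoint == tp)
    if (length(idx) < 2L) next
    vals <- unlist(fc$folds[idx])
    grps <- rep(fc$condition[idx], lengths(fc$folds[idx]))
    lt <- anovaTukey(vals, grps, alpha)$letters
    fc$letter[idx] <- lt[fc$condition[idx]]
  }
  if (!is.null(out))
    utils::write.table(fc[, setdiff(names(fc), "folds")], out, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  fc
}

#' Generate a full synthetic analysis bundle on disk
#'
#' Writes genome FASTA, GFF3, proteome FASTA, promoter FASTA, a Ct table and
#' a ground-truth manifest (JSON) into \code{outDir}, ready for
#' [runIdentify()] and friends.
#'
#' @param outDir output directory (created if needed).
#' @param nLoci,isoforms,groups see [simulateGenomeWithLoci()].
#' @param seed integer seed.
#' @return named character vector of the written paths, invisibly.
#' @export
runSimulate <- function(outDir, nLoci = 5L, isoforms = c(3L, 2L, 1L, 2L, 1L),
                        groups = c("II", "I", "III", "decoy", "II"),
                        seed = 1L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulateGenomeWithLoci(nLoci, isoforms, groups, seed = seed)
  ct <- simulateCtTable(c(t30min = 25, t4h = 1.78, t24h = 1.5), seed = seed)
  paths <- c(genome = file.path(outDir, "genome.fa"),
             gff3 = file.path(outDir, "annotation.gff3"),
             proteome = file.path(outDir, "proteome.fa"),
             promoters = file.path(outDir, "promoters.fa"),
             ct = file.path(outDir, "ct_table.tsv"),
             manifest = file.path(outDir, "manifest.json"))
  writeFasta(sim$bundle@contigs, paths[["genome"]])
  writeBundleGff3(sim$bundle, paths[["gff3"]])
  writeFasta(sim$bundle@proteome, paths[["proteome"]])
  proms <- Biostrings::DNAStringSet(vapply(sim$manifest, `[[`, character(1),
                                           "promoter"))
  names(proms) <- names(sim$manifest)
  writeFasta(proms, paths[["promoters"]])
  utils::write.table(ct, paths[["ct"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(sim$manifest, paths[["manifest"]], auto_unbox = TRUE)
  } else {
    writeLines(utils::capture.output(utils::str(sim$manifest)),
               paths[["manifest"]])
  }
  invisible(paths)
}
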