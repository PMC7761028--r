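# Residues used for neutral protein background: no W (kills spurious
# heptapeptides), no C/H (kills spurious zinc fingers), so planted domains
# are provably the only WRKY evidence in a simulated protein.
SAFE_AA <- setdiff(AA20, c("W", "C", "H", "M"))

rand_aa <- function(n) paste(sample(SAFE_AA, n, replace = TRUE), collapse = "")

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# one complete WRKY domain unit: heptapeptide + spacer + zinc finger
domain_unit <- function(zfClass = c("C2H2", "C2HC"), spacerLen = 10L) {
  zfClass <- match.arg(zfClass)
  last <- if (zfClass == "C2H2") "H" else "C"
  paste0("WRKYGQK", rand_aa(spacerLen),
         "C", rand_aa(5L), "C", rand_aa(23L), "H", rand_aa(1L), last)
}

#' Simulate a proteome with planted WRKY domains
#'
#' Group-I proteins carry two complete heptapeptide + C2H2 units, group-II
#' one C2H2 unit, group-III one C2HC unit; decoys contain no heptapeptide.
#' Group-II members are mutated copies of per-subgroup centroid domains
#' (IIa-IIe), so subgroup structure is recoverable phylogenetically.
#' Background residues exclude W, C, H and M, making the planted signals
#' the only domain evidence.  Fully deterministic per seed.
#'
#' @param nGroup1,nGroup3,nDecoys protein counts.
#' @param nGroup2 either a single count split round-robin over subgroups
#'   IIa-IIe, or a length-5 named/ordered vector of per-subgroup counts.
#' @param lengthRange min/max protein length (must fit the domains).
#' @param mutationsPerCopy point mutations applied to each group-II copy of
#'   its subgroup centroid (in non-critical positions).
#' @param seed integer seed.
#' @return list with \code{proteome} (\linkS4class{AAStringSet}),
#'   \code{references} (the five subgroup centroid proteins, named
#'   \code{ref_IIa..ref_IIe}), and \code{manifest} (data.frame: protein_id,
#'   group, subgroup, domain offsets/classes as comma strings).
#' @export
simulateWrkyProteome <- function(nGroup1 = 10L, nGroup2 = 20L, nGroup3 = 5L,
                                 nDecoys = 15L, lengthRange = c(150L, 300L),
                                 mutationsPerCopy = 2L, seed = 1L) {
  stopifnot(nGroup1 >= 0, all(nGroup2 >= 0), nGroup3 >= 0, nDecoys >= 0)
  if (lengthRange[1] < 120L)
    stop("lengthRange too short to host a WRKY domain")
  subgroups <- c("IIa", "IIb", "IIc", "IId", "IIe")
  n2 <- if (length(nGroup2) == 5L) as.integer(nGroup2)
        else as.integer(table(factor(subgroups[(seq_len(nGroup2) - 1L) %% 5L + 1L],
                                     levels = subgroups)))
  with_seed(seed, {
    # subgroup centroids: domain unit + subgroup-specific flank
    centroids <- stats::setNames(lapply(subgroups, function(sg)
      paste0(domain_unit("C2H2"), rand_aa(40L))), subgroups)
    rows <- list(); seqs <- character(); k <- 0L
    addProtein <- function(id, seqparts, group, subgroup) {
      # seqparts: list(prefix, units (character vector), suffix-filler len)
      prefix <- seqparts$prefix
      body <- seqparts$body
      minLen <- nchar(prefix) + nchar(body)
      total <- max(minLen, sample(lengthRange[1]:lengthRange[2], 1L))
      seqv <- paste0(prefix, body, rand_aa(total - minLen))
      seqs[[id]] <<- paste0("M", seqv)
      hits <- findWrkyDomains(seqs[[id]])
      rows[[length(rows) + 1L]] <<- data.frame(
        protein_id = id, group = group, subgroup = subgroup,
        n_domains = sum(hits$complete),
        hepta_starts = paste(hits$hepta_start, collapse = ","),
        zf_classes = paste(hits$zf_class, collapse = ","),
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(nGroup1)) {
      k <- k + 1L
      addProtein(sprintf("G1_%03d", i),
                 list(prefix = rand_aa(10L),
                      body = paste0(domain_unit("C2H2"), rand_aa(25L),
                                    domain_unit("C2H2"))),
                 "I", "none")
    }
    for (s in seq_along(subgroups)) {
      sg <- subgroups[s]
      for (i in seq_len(n2[s])) {
        cen <- centroids[[sg]]
        # mutate flank positions only (after the zinc finger)
        flankStart <- nchar(cen) - 39L
        pos <- sample(flankStart:nchar(cen), mutationsPerCopy)
        for (p in pos) substr(cen, p, p) <- sample(SAFE_AA, 1L)
        addProtein(sprintf("G2%s_%03d", sg, i),
                   list(prefix = rand_aa(10L), body = cen), "II", sg)
      }
    }
    for (i in seq_len(nGroup3)) {
      addProtein(sprintf("G3_%03d", i),
                 list(prefix = rand_aa(10L), body = domain_unit("C2HC")),
                 "III", "none")
    }
    for (i in seq_len(nDecoys)) {
      len <- sample(lengthRange[1]:lengthRange[2], 1L)
      id <- sprintf("DEC_%03d", i)
      seqs[[id]] <- paste0("M", rand_aa(len))
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = id, group = "decoy", subgroup = "none", n_domains = 0L,
        hepta_starts = "", zf_classes = "", stringsAsFactors = FALSE)
    }
    refs <- Biostrings::AAStringSet(vapply(subgroups, function(sg)
      paste0("M", rand_aa(10L), centroids[[sg]]), character(1)))
    names(refs) <- paste0("ref_", subgroups)
    manifest <- do.call(rbind, rows)
    rownames(manifest) <- NULL
    list(proteome = Biostrings::AAStringSet(seqs), references = refs,
         manifest = manifest)
  })
}

## ---- promoter simulation ------------------------------------------------

pattern_regexes <- function(motifs) {
  iupac <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
             S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
             D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  unlist(lapply(motifs, function(pats) vapply(pats, function(p)
    paste(iupac[strsplit(p, "")[[1L]]], collapse = ""), character(1))))
}

# random DNA of length n containing no forward-strand match of any regex;
# built base-by-base, resampling a base whenever it completes a match
clean_background <- function(n, regexes, gc = 0.4, maxPat = 12L) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  out <- character(n)
  for (i in seq_len(n)) {
    for (try in seq_len(100L)) {
      out[i] <- sample(names(probs), 1L, prob = probs)
      tail <- paste(out[max(1L, i - maxPat + 1L):i], collapse = "")
      hit <- any(vapply(regexes, function(rx)
        grepl(paste0(rx, "$"), tail), logical(1)))
      if (!hit) break
      if (try == 100L) stop("could not sample motif-free background")
    }
  }
  paste(out, collapse = "")
}

#' Simulate promoters with planted cis-element counts
#'
#' Backgrounds are rejection-sampled to contain no forward-strand match of
#' any built-in motif, then the requested elements are planted at
#' non-overlapping positions (and re-planted if a junction accidentally
#' creates an extra match), so the manifest counts are exact by
#' construction.  Double W-boxes (\code{TTGACTTTGACT}) are planted at the
#' requested ATG-relative offsets and contribute two W-box matches each.
#'
#' @param plantedCounts named list (per gene) of named integer vectors of
#'   counts per built-in motif, e.g.
#'   \code{list(g1 = c("W-box" = 5, "MeJa-RE" = 5))}.
#' @param doubleWbox named list (per gene) of ATG-relative start offsets of
#'   planted double W-boxes (negative integers), e.g.
#'   \code{list(g1 = -800)}.
#' @param length promoter length (default 3000).
#' @param gc background GC content.
#' @param seed integer seed.
#' @return list with \code{promoters} (\linkS4class{DNAStringSet}) and
#'   \code{manifest} (list: per gene expected per-motif counts and double
#'   W-box offsets).
#' @export
simulatePromoters <- function(plantedCounts, doubleWbox = list(),
                              length = 3000L, gc = 0.4, seed = 1L) {
  motifs <- builtinMotifs()
  regexes <- pattern_regexes(motifs)
  genes <- names(plantedCounts)
  if (is.null(genes)) stop("plantedCounts must be a named list")
  with_seed(seed, {
    proms <- character(0)
    expected <- list()
    for (g in genes) {
      counts <- plantedCounts[[g]]
      bad <- setdiff(names(counts), names(motifs))
      if (length(bad)) stop("unknown motif(s): ", paste(bad, collapse = ", "))
      dwb <- if (g %in% names(doubleWbox)) as.integer(doubleWbox[[g]])
             else integer()
      # build the list of elements to place
      elems <- character()
      for (nm in names(counts)) {
        if (counts[[nm]] > 0L)
          elems <- c(elems, vapply(seq_len(counts[[nm]]), function(i) {
            pats <- motifs[[nm]]
            pat <- pats[sample.int(length(pats), 1L)]
            concrete_iupac(pat)
          }, character(1)))
      }
      need <- sum(nchar(elems)) + length(dwb) * 12L
      if (need > length) stop("infeasible packing for gene ", g)
      done <- FALSE
      for (attempt in seq_len(50L)) {
        bg <- clean_background(length, regexes, gc)
        prom <- bg
        used <- IRanges::IRanges()
        ok <- TRUE
        # double W-boxes at fixed offsets first
        for (off in dwb) {
          st <- length + 1L + off
          if (st < 1L || st + 11L > length) stop("double W-box offset out of range")
          ir <- IRanges::IRanges(st, st + 11L)
          if (length(IRanges::findOverlaps(ir, used)) > 0L) { ok <- FALSE; break }
          substr(prom, st, st + 11L) <- "TTGACTTTGACT"
          used <- c(used, ir)
        }
        if (ok) for (e in elems) {
          placed <- FALSE
          for (t in seq_len(200L)) {
            st <- sample.int(length - nchar(e) + 1L, 1L)
            ir <- IRanges::IRanges(st, st + nchar(e) - 1L)
            # keep a 12-bp guard band so junctions cannot create new motifs
            pad <- IRanges::IRanges(max(1L, IRanges::start(ir) - 12L),
                                    min(length, IRanges::end(ir) + 12L))
            if (length(IRanges::findOverlaps(pad, used)) == 0L) {
              substr(prom, st, st + nchar(e) - 1L) <- e
              used <- c(used, ir)
              placed <- TRUE
              break
            }
          }
          if (!placed) { ok <- FALSE; break }
        }
        if (!ok) next
        # verify exact counts (junction artifacts force a resample)
        exp_counts <- vapply(names(motifs), function(nm) {
          base <- if (nm %in% names(counts)) counts[[nm]] else 0L
          as.integer(base + if (nm == "W-box") 2L * length(dwb) else 0L)
        }, integer(1))
        got <- reportCounts(countTable(stats::setNames(list(prom), g),
                                       motifs))[1L, ]
        bip <- findBipartiteWbox(prom)
        if (identical(unname(got), unname(exp_counts)) &&
            identical(sort(bip$offset), sort(dwb))) {
          proms[[g]] <- prom
          expected[[g]] <- list(counts = exp_counts, double_wbox = dwb)
          done <- TRUE
          break
        }
      }
      if (!done) stop("could not realize planted counts for ", g)
    }
    out <- Biostrings::DNAStringSet(proms)
    names(out) <- genes
    list(promoters = out, manifest = expected)
  })
}

# draw a concrete DNA word from an IUPAC pattern
concrete_iupac <- function(pat) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                K = c("G", "T"), M = c("A", "C"))
  paste(vapply(strsplit(pat, "")[[1L]], function(ch) {
    opts <- iupac[[ch]]
    opts[sample.int(length(opts), 1L)]
  }, character(1)), collapse = "")
}

## ---- genome simulation --------------------------------------------------

CODON <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT", Q = "CAA",
           E = "GAA", G = "GGT", H = "CAT", I = "ATT", L = "CTT", K = "AAA",
           M = "ATG", F = "TTT", P = "CCT", S = "TCT", T = "ACT", W = "TGG",
           Y = "TAT", V = "GTT")

reverse_translate <- function(protein) {
  paste(CODON[strsplit(protein, "")[[1L]]], collapse = "")
}

#' Simulate a genome with multi-isoform WRKY loci
#'
#' Lays out \code{nLoci} gene loci on one contig, spaced at least 5 kb
#' apart, each with the requested number of isoforms sharing (overlapping)
#' CDS.  Each locus encodes a planted WRKY protein of the requested group
#' (or a domain-free decoy), reverse-translated with a fixed codon table and
#' split over exons; a motif-free promoter of the requested length is
#' planted immediately upstream of the ATG on the coding strand.  Loci
#' alternate between the two strands.
#'
#' @param nLoci number of loci (>= 1).
#' @param isoforms integer vector (recycled) of isoform counts per locus.
#' @param groups character vector (recycled) over
#'   \code{c("I","II","III","decoy")}.
#' @param promoterLength planted promoter length (default 3000).
#' @param seed integer seed.
#' @return list with \code{bundle} (a [GenomeBundle-class]) and
#'   \code{manifest} (list: per locus transcript ids, representative,
#'   group, promoter string).
#' @export
simulateGenomeWithLoci <- function(nLoci = 5L, isoforms = c(3L, 2L, 1L, 2L, 1L),
                                   groups = "II", promoterLength = 3000L,
                                   seed = 1L) {
  stopifnot(nLoci >= 1L)
  isoforms <- rep_len(as.integer(isoforms), nLoci)
  groups <- rep_len(groups, nLoci)
  regexes <- pattern_regexes(builtinMotifs())
  with_seed(seed, {
    contigParts <- character()
    pos <- 1L
    txRows <- list(); exonsL <- list(); cdsL <- list()
    prots <- character(); manifest <- list()
    spacer <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
    for (li in seq_len(nLoci)) {
      gid <- sprintf("gene%02d", li)
      grp <- groups[li]
      body <- switch(grp,
        I = paste0(domain_unit("C2H2"), rand_aa(25L), domain_unit("C2H2")),
        II = domain_unit("C2H2"),
        III = domain_unit("C2HC"),
        decoy = rand_aa(80L))
      protein <- paste0("M", rand_aa(5L), body, rand_aa(30L))
      cdsNt <- reverse_translate(protein)
      # exon boundaries at codon multiples
      nCodon <- nchar(cdsNt) / 3L
      nEx <- sample(2:3, 1L)
      cuts <- sort(sample(seq_len(nCodon - 1L), nEx - 1L)) * 3L
      pieceStart <- c(1L, cuts + 1L)
      pieceEnd <- c(cuts, nchar(cdsNt))
      intronSeqs <- vapply(seq_len(nEx - 1L), function(i)
        paste0("GT", spacer(sample(60:120, 1L)), "AG"), character(1))
      prom <- clean_background(promoterLength, regexes)
      # assemble coding-strand block: promoter + exon/intron mosaic
      blockGene <- ""
      exRel <- matrix(0L, nEx, 2L)  # exon coords relative to gene body start
      at <- 0L
      for (e in seq_len(nEx)) {
        piece <- substr(cdsNt, pieceStart[e], pieceEnd[e])
        exRel[e, ] <- c(at + 1L, at + nchar(piece))
        blockGene <- paste0(blockGene, piece)
        at <- at + nchar(piece)
        if (e < nEx) {
          blockGene <- paste0(blockGene, intronSeqs[e])
          at <- at + nchar(intronSeqs[e])
        }
      }
      block <- paste0(prom, blockGene)
      L <- nchar(block)
      strand <- if (li %% 2L == 1L) "+" else "-"
      o <- pos + 5000L  # >= 5 kb inter-locus spacing
      contigParts <- c(contigParts, spacer(o - pos),
                       if (strand == "+") block else
                         as.character(Biostrings::reverseComplement(
                           Biostrings::DNAString(block))))
      blockStart <- o
      pos <- o + L
      # genome coordinates of each exon piece
      exGenome <- t(apply(exRel, 1L, function(k) {
        k <- k + promoterLength  # position within block
        if (strand == "+") c(blockStart + k[1L] - 1L, blockStart + k[2L] - 1L)
        else c(blockStart + L - k[2L], blockStart + L - k[1L])
      }))
      txids <- character(isoforms[li])
      for (iso in seq_len(isoforms[li])) {
        keep <- if (iso == 1L) seq_len(nEx) else
          seq_len(max(1L, nEx - (iso - 1L)))
        tid <- sprintf("%s.t%d", gid, iso)
        pid <- sprintf("%s.p%d", gid, iso)
        txids[iso] <- tid
        gr <- GenomicRanges::GRanges("chr1",
          IRanges::IRanges(exGenome[keep, 1L], exGenome[keep, 2L]),
          strand = strand)
        gr <- GenomicRanges::sort(gr)
        exonsL[[tid]] <- gr
        cdsL[[tid]] <- gr
        txRows[[length(txRows) + 1L]] <- data.frame(
          gene_id = gid, transcript_id = tid, protein_id = pid,
          seqid = "chr1", strand = strand, stringsAsFactors = FALSE)
        cdsIso <- paste(vapply(keep, function(e)
          substr(cdsNt, pieceStart[e], pieceEnd[e]), character(1)),
          collapse = "")
        prots[[pid]] <- as.character(Biostrings::translate(
          Biostrings::DNAString(cdsIso)))
      }
      manifest[[gid]] <- list(transcripts = txids,
                              representative = txids[1L],
                              group = grp, strand = strand,
                              promoter = prom)
    }
    contigParts <- c(contigParts, spacer(500L))
    contigs <- Biostrings::DNAStringSet(paste(contigParts, collapse = ""))
    names(contigs) <- "chr1"
    bundle <- genomeBundle(
      contigs,
      do.call(rbind, txRows),
      GenomicRanges::GRangesList(exonsL),
      GenomicRanges::GRangesList(cdsL),
      Biostrings::AAStringSet(prots))
    list(bundle = bundle, manifest = manifest)
  })
}

#' Simulate a replicate qPCR Ct table
#'
#' Draws target and reference Ct values so that the expected 2^-ddCt of the
#' treated condition against the control calibrator equals the requested
#' fold change at each timepoint, with Gaussian replicate noise on the
#' target Ct and optional drift on the reference gene.
#'
#' @param trueFolds named numeric vector: fold change per timepoint
#'   (treated vs control), all > 0.
#' @param sd Gaussian noise SD on each target Ct (cycles).
#' @param referenceDriftSd SD of reference-gene drift per sample.
#' @param replicates replicates per condition/timepoint (>= 2).
#' @param seed integer seed.
#' @return data.frame Ct table (columns sample, condition, timepoint, gene,
#'   replicate, ct) with attribute \code{"trueFolds"}.
#' @export
simulateCtTable <- function(trueFolds, sd = 0.1, referenceDriftSd = 0,
                            replicates = 3L, seed = 1L) {
  if (any(trueFolds <= 0)) stop("fold changes must be > 0")
  if (replicates < 2L) stop("need >= 2 replicates")
  tps <- names(trueFolds)
  if (is.null(tps)) tps <- paste0("t", seq_along(trueFolds))
  with_seed(seed, {
    rows <- list()
    for (t in seq_along(trueFolds)) {
      for (cond in c("control", "treated")) {
        shift <- if (cond == "treated") -log2(trueFolds[[t]]) else 0
        for (r in seq_len(replicates)) {
          refCt <- 20 + stats::rnorm(1L, 0, referenceDriftSd)
          tgtCt <- refCt + 5 + shift + stats::rnorm(1L, 0, sd)
          sid <- sprintf("%s_%s_r%d", cond, tps[t], r)
          rows[[length(rows) + 1L]] <- data.frame(
            sample = sid, condition = cond, timepoint = tps[t],
            gene = c("target", "reference"), replicate = r,
            ct = c(tgtCt, refCt), stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "trueFolds") <- trueFolds
    out
  })
}
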