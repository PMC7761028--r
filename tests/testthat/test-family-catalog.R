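two_tx_bundle <- function(strand2 = "+", sameLocus = TRUE) {
  # two transcripts; overlap controlled by sameLocus/strand2
  gr1 <- GenomicRanges::GRanges("c1", IRanges::IRanges(101, 400), strand = "+")
  start2 <- if (sameLocus) 301 else 20101
  gr2 <- GenomicRanges::GRanges("c1", IRanges::IRanges(start2, start2 + 299),
                                strand = strand2)
  genomeBundle(
    Biostrings::DNAStringSet(c(c1 = strrep("A", 30000))),
    data.frame(gene_id = c("g1", "g2"), transcript_id = c("t1", "t2"),
               protein_id = c("p1", "p2"), seqid = "c1",
               strand = c("+", strand2), stringsAsFactors = FALSE),
    GenomicRanges::GRangesList(t1 = gr1, t2 = gr2),
    GenomicRanges::GRangesList(t1 = gr1, t2 = gr2),
    Biostrings::AAStringSet(c(p1 = strrep("M", 60), p2 = strrep("M", 40))))
}

test_that("locus dedup follows single-linkage same-strand CDS overlap", {
  cl <- dedupeByLocus(two_tx_bundle())
  expect_equal(max(cl$cluster), 1L)
  expect_identical(cl$protein_id[cl$representative], "p1")  # longest protein

  # same coordinates, opposite strands: two loci
  cl2 <- dedupeByLocus(two_tx_bundle(strand2 = "-", sameLocus = TRUE))
  expect_equal(max(cl2$cluster), 2L)

  # disjoint coordinates: two loci
  cl3 <- dedupeByLocus(two_tx_bundle(sameLocus = FALSE))
  expect_equal(max(cl3$cluster), 2L)
})

test_that("locus dedup recovers the planted cluster structure", {
  sim <- simulateGenomeWithLoci(nLoci = 5, isoforms = c(3, 2, 1, 2, 1),
                                seed = 5)
  cl <- dedupeByLocus(sim$bundle)
  expect_equal(nrow(cl), 9L)
  expect_equal(max(cl$cluster), 5L)
  for (gid in names(sim$manifest)) {
    members <- cl$transcript_id[cl$gene_id == gid]
    expect_setequal(members, sim$manifest[[gid]]$transcripts)
    expect_equal(length(unique(cl$cluster[cl$gene_id == gid])), 1L)
    expect_identical(cl$transcript_id[cl$gene_id == gid & cl$representative],
                     sim$manifest[[gid]]$representative)
  }
})

test_that("catalog keeps only domain-bearing representatives with correct groups", {
  sim <- simulateWrkyProteome(nGroup1 = 10, nGroup2 = 20, nGroup3 = 5,
                              nDecoys = 15, seed = 7)
  # wrap the proteome as single-exon loci far apart
  n <- length(sim$proteome)
  starts <- seq(1000L, by = 10000L, length.out = n)
  grl <- GenomicRanges::GRangesList(lapply(seq_len(n), function(i)
    GenomicRanges::GRanges("c1", IRanges::IRanges(starts[i], starts[i] + 299L),
                           strand = "+")))
  ids <- names(sim$proteome)
  names(grl) <- paste0("t_", ids)
  bundle <- genomeBundle(
    Biostrings::DNAStringSet(c(c1 = strrep("A", max(starts) + 1000L))),
    data.frame(gene_id = paste0("g_", ids), transcript_id = paste0("t_", ids),
               protein_id = ids, seqid = "c1", strand = "+",
               stringsAsFactors = FALSE),
    grl, grl, sim$proteome)
  cat <- buildCatalog(bundle)
  e <- catalogEntries(cat)
  expect_equal(nrow(e), 35L)  # decoys excluded
  truth <- sim$manifest
  m <- match(e$protein_id, truth$protein_id)
  expect_false(anyNA(m))
  expect_identical(e$group, truth$group[m])
  gc <- groupCounts(cat)
  expect_equal(unname(gc[c("I", "II", "III")]), c(10L, 20L, 5L))
  expect_equal(sum(gc), nrow(e))  # groups partition the catalog
})

test_that("a protein with two complete domains lands in group I", {
  unit <- paste0("WRKYGQK", strrep("A", 4), "C", strrep("A", 5),
                 "C", strrep("A", 23), "H", "A", "H")
  p <- paste0("M", unit, strrep("G", 20), unit, "GG")
  h <- findWrkyDomains(p)
  expect_equal(sum(h$complete), 2L)
  b <- two_tx_bundle(sameLocus = FALSE)
  b@proteome <- Biostrings::AAStringSet(c(p1 = p, p2 = strrep("A", 40)))
  e <- catalogEntries(buildCatalog(b))
  expect_equal(nrow(e), 1L)
  expect_identical(e$group, "I")
})

test_that("partial-domain entries appear only with keepPartial", {
  b <- two_tx_bundle(sameLocus = FALSE)
  partial <- paste0("M", strrep("A", 10), "WRKYGQK", strrep("A", 60))
  b@proteome <- Biostrings::AAStringSet(c(p1 = partial, p2 = strrep("A", 40)))
  expect_equal(nrow(catalogEntries(buildCatalog(b))), 0L)
  e <- catalogEntries(buildCatalog(b, keepPartial = TRUE))
  expect_equal(nrow(e), 1L)
  expect_identical(e$flags, "partial_domain")
  expect_identical(e$group, "unclassified")
})

test_that("subgroup assignment recovers planted subgroups from the tree", {
  sim <- simulateWrkyProteome(nGroup1 = 0, nGroup2 = c(4, 4, 4, 4, 4),
                              nGroup3 = 0, nDecoys = 0, seed = 17)
  seqs <- c(sim$proteome, sim$references)
  aln <- progressiveMsa(seqs)
  tree <- njTree(pdistance(aln))
  refLabels <- stats::setNames(sub("ref_", "", names(sim$references)),
                               names(sim$references))
  entries <- data.frame(
    protein_id = names(sim$proteome), gene_id = names(sim$proteome),
    transcript_id = names(sim$proteome), seqid = "c1", strand = "+",
    locus_start = 1L, locus_end = 2L, n_domains = 1L, zf_class = "C2H2",
    group = "II", subgroup = "none", flags = "", stringsAsFactors = FALSE)
  cat <- new("WrkyCatalog", entries = entries)
  out <- catalogEntries(assignSubgroups(cat, tree, refLabels, seqs))
  truth <- sim$manifest$subgroup[match(out$protein_id,
                                       sim$manifest$protein_id)]
  expect_gte(mean(out$subgroup == truth), 0.95)
})

test_that("subgroup assignment validates its references and breaks ties deterministically", {
  tree <- readNewick("((q:1,refA:1):1,(refB:1,x:1):1);")
  refs <- c(refA = "IIa", refB = "IIb")
  entries <- data.frame(
    protein_id = "q", gene_id = "q", transcript_id = "q", seqid = "c",
    strand = "+", locus_start = 1L, locus_end = 2L, n_domains = 1L,
    zf_class = "C2H2", group = "II", subgroup = "none", flags = "",
    stringsAsFactors = FALSE)
  cat <- new("WrkyCatalog", entries = entries)
  expect_error(assignSubgroups(cat, tree, refs), "IIc")

  allRefs <- c(refA = "IIa", refB = "IIb", refC = "IIc", refD = "IId",
               refE = "IIe")
  # q equidistant from refA and refB: tie resolves to the reference sharing
  # the longer common substring with q
  tieTree <- readNewick(
    "(q:1,refA:2,refB:2,(refC:1,refD:1,refE:1):5);")
  D <- ape::cophenetic.phylo(tieTree)
  expect_equal(D["q", "refA"], D["q", "refB"])
  seqs <- Biostrings::AAStringSet(c(q = "MKLVVNPAG", refA = "MKAAAAAAA",
                                    refB = "MKLVVNPTT", refC = "MCC",
                                    refD = "MDD", refE = "MEE"))
  out <- catalogEntries(assignSubgroups(cat, tieTree, allRefs, seqs))
  expect_identical(out$subgroup, "IIb")
})
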