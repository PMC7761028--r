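test_that("FASTA reading takes ids from headers and round-trips losslessly", {
  tf <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a some description", "ACGT"), tf)
  x <- readFasta(tf, "dna")
  expect_length(x, 1L)
  expect_identical(names(x), "a")
  expect_identical(as.character(x[[1]]), "ACGT")
  expect_identical(S4Vectors::mcols(x)$description, "some description")

  empty <- withr::local_tempfile(fileext = ".fa")
  file.create(empty)
  expect_length(readFasta(empty, "dna"), 0L)

  set.seed(7)
  recs <- Biostrings::AAStringSet(vapply(1:3, function(i) rand_protein(80),
                                         character(1)))
  names(recs) <- c("p1", "p2", "p3")
  out <- withr::local_tempfile(fileext = ".fa")
  writeFasta(recs, out)
  back <- readFasta(out, "protein")
  expect_identical(names(back), names(recs))
  expect_identical(as.character(back), as.character(recs))
})

make_gff <- function(lines) {
  tf <- withr::local_tempfile(fileext = ".gff3", .local_envir = parent.frame())
  writeLines(c("##gff-version 3", lines), tf)
  tf
}

test_that("GFF3 parsing resolves parentage and keeps interval lengths", {
  gff <- make_gff(c(
    "chr1\tsrc\tgene\t11\t60\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t11\t60\t.\t+\t.\tID=t1;Parent=g1;protein_id=p1",
    "chr1\tsrc\texon\t11\t20\t.\t+\t.\tID=t1.e1;Parent=t1",
    "chr1\tsrc\texon\t41\t60\t.\t+\t.\tID=t1.e2;Parent=t1",
    "chr1\tsrc\tCDS\t11\t20\t.\t+\t.\tID=t1.c1;Parent=t1",
    "chr1\tsrc\tmRNA\t11\t30\t.\t+\t.\tID=t2;Parent=g1;protein_id=p2",
    "chr1\tsrc\texon\t11\t30\t.\t+\t.\tID=t2.e1;Parent=t2"))
  ann <- readGff3(gff)
  expect_equal(nrow(ann$transcripts), 2L)
  expect_setequal(ann$transcripts$gene_id, "g1")
  e1 <- ann$exons[["t1"]]
  # 1-based inclusive: an 11..20 exon is 10 bp
  expect_equal(GenomicRanges::width(e1), c(10L, 20L))
  expect_equal(GenomicRanges::start(e1), c(11L, 41L))
  expect_true("t1" %in% names(ann$cds))
  expect_false("t2" %in% names(ann$cds))
})

test_that("GFF3 orphans and unknown strands are rejected", {
  orphan <- make_gff(c(
    "chr1\tsrc\tmRNA\t1\t10\t.\t+\t.\tID=t1",
    "chr1\tsrc\texon\t1\t10\t.\t+\t.\tParent=t1",
    "chr1\tsrc\tCDS\t1\t10\t.\t+\t.\tParent=tX"))
  expect_error(readGff3(orphan), "unresolved mRNA parent")

  nostrand <- make_gff(c(
    "chr1\tsrc\tmRNA\t1\t10\t.\t.\t.\tID=t1",
    "chr1\tsrc\texon\t1\t10\t.\t.\t.\tParent=t1"))
  expect_error(readGff3(nostrand), "strand")
})

toy_bundle <- function(contig, cdsStart, cdsEnd, strand = "+") {
  gr <- GenomicRanges::GRanges("c1", IRanges::IRanges(cdsStart, cdsEnd),
                               strand = strand)
  genomeBundle(
    Biostrings::DNAStringSet(c(c1 = contig)),
    data.frame(gene_id = "g", transcript_id = "t", protein_id = "p",
               seqid = "c1", strand = strand, stringsAsFactors = FALSE),
    GenomicRanges::GRangesList(t = gr),
    GenomicRanges::GRangesList(t = gr),
    Biostrings::AAStringSet(c(p = "M")))
}

test_that("promoter extraction is anchored at the ATG on the coding strand", {
  set.seed(11)
  contig <- rand_dna(6000)
  # '+' gene with CDS starting at 5001: promoter = contig[2001..5000]
  b <- toy_bundle(contig, 5001L, 5030L, "+")
  p <- extractPromoter(b, "t", 3000L)
  expect_identical(as.character(p[[1]]), substr(contig, 2001L, 5000L))

  # '-' gene with CDS ending at 100: promoter = revcomp(contig[101..3100])
  b2 <- toy_bundle(contig, 71L, 100L, "-")
  p2 <- extractPromoter(b2, "t", 3000L)
  expect_identical(as.character(p2[[1]]),
                   revcomp_chr(substr(contig, 101L, 3100L)))

  # truncation at the contig edge keeps what exists and warns
  b3 <- toy_bundle(contig, 501L, 530L, "+")
  expect_warning(p3 <- extractPromoter(b3, "t", 3000L), "truncated")
  expect_equal(Biostrings::width(p3), 500L)
})

test_that("promoter extraction is strand-consistent under reverse complement", {
  set.seed(13)
  contig <- rand_dna(5000)
  n <- nchar(contig)
  s <- 4201L; e <- 4260L
  fwd <- extractPromoter(toy_bundle(contig, s, e, "+"), "t", 1000L)
  rcContig <- revcomp_chr(contig)
  # mirrored coordinates of [s, e] in the reverse-complemented contig
  rb <- toy_bundle(rcContig, n - e + 1L, n - s + 1L, "-")
  rev <- extractPromoter(rb, "t", 1000L)
  expect_identical(as.character(fwd[[1]]), as.character(rev[[1]]))
})

test_that("Newick round trip preserves topology and branch lengths", {
  D <- matrix(c(0, 5, 9, 9, 5, 0, 10, 10, 9, 10, 0, 8, 9, 10, 8, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- njTree(D)
  tf <- withr::local_tempfile(fileext = ".nwk")
  writeNewick(tr, tf)
  back <- readNewick(tf)
  expect_true(same_topology(tr, back))
  expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-9)

  star <- readNewick("(a:1,b:1,c:1);")
  expect_identical(sort(star$tip.label), c("a", "b", "c"))
})

test_that("catalog TSV export writes a header-only file for empty catalogs", {
  empty <- new("WrkyCatalog", entries = data.frame(
    protein_id = character(), gene_id = character(),
    transcript_id = character(), seqid = character(), strand = character(),
    locus_start = integer(), locus_end = integer(), n_domains = integer(),
    zf_class = character(), group = character(), subgroup = character(),
    flags = character(), stringsAsFactors = FALSE))
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeCatalogTsv(empty, tf)
  lines <- readLines(tf)
  expect_length(lines, 1L)
  expect_match(lines[1], "^protein_id\tgene_id\t")
})
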