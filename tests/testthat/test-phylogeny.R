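test_that("pairwise alignment handles identity, mismatch and errors", {
  a <- pairwiseGlobalAlign("WRKYGQK", "WRKYGQK")
  expect_equal(a$identity, 1)
  B <- wrkymine:::blosum62()
  expect_equal(a$score, sum(diag(B[strsplit("WRKYGQK", "")[[1]],
                                   strsplit("WRKYGQK", "")[[1]]])))
  b <- pairwiseGlobalAlign("WRKYGQK", "WRKYGKK")
  expect_equal(b$identity, 6 / 7)
  expect_error(pairwiseGlobalAlign("", "A"), "empty")
})

test_that("alignment scores equal the exhaustive-enumeration oracle", {
  B <- wrkymine:::blosum62()
  set.seed(23)
  for (i in 1:12) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    s1 <- rand_protein(n1); s2 <- rand_protein(n2)
    got <- pairwiseGlobalAlign(s1, s2, gapOpen = -10, gapExtend = -1)$score
    want <- oracle_align_score(s1, s2, B, -10, -1)
    expect_equal(got, want, info = paste(s1, s2))
  }
  # also under a different gap regime
  for (i in 1:5) {
    s1 <- rand_protein(4); s2 <- rand_protein(5)
    got <- pairwiseGlobalAlign(s1, s2, gapOpen = -5, gapExtend = -2)$score
    expect_equal(got, oracle_align_score(s1, s2, B, -5, -2))
  }
})

test_that("alignment scores agree with an independent aligner", {
  set.seed(29)
  for (i in 1:8) {
    s1 <- rand_protein(sample(10:40, 1)); s2 <- rand_protein(sample(10:40, 1))
    got <- pairwiseGlobalAlign(s1, s2, gapOpen = -10, gapExtend = -1)$score
    # Biostrings parameterizes affine gaps as open+extend for the first
    # gapped position
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(s1), Biostrings::AAString(s2),
      substitutionMatrix = "BLOSUM62", gapOpening = 9, gapExtension = 1,
      type = "global", scoreOnly = TRUE)
    expect_equal(got, ref)
  }
})

test_that("progressive MSA aligns easy cases correctly", {
  same <- Biostrings::AAStringSet(c(a = "MKLV", b = "MKLV"))
  aln <- progressiveMsa(same)
  expect_identical(as.character(aln), c(a = "MKLV", b = "MKLV"))

  # one internal deletion: one gap in that record only
  set.seed(3)
  base <- rand_protein(40)
  del <- paste0(substr(base, 1, 19), substr(base, 21, 40))
  trio <- Biostrings::AAStringSet(c(x = base, y = base, z = del))
  a3 <- progressiveMsa(trio)
  expect_equal(unique(Biostrings::width(a3)), 40L)
  expect_identical(as.character(a3[["x"]]), base)
  expect_equal(sum(strsplit(as.character(a3[["z"]]), "")[[1]] == "-"), 1L)

  # planted conserved block stays gap-free in every record; flanks use
  # letters disjoint from the block so the planted columns are unambiguous
  block <- "WRKYGQKEVKG"
  set.seed(5)
  flank <- function(n) paste(sample(c("S", "T", "P", "N", "D", "H"), n,
                                    replace = TRUE), collapse = "")
  recs <- Biostrings::AAStringSet(vapply(1:4, function(i)
    paste0(flank(sample(5:15, 1)), block, flank(sample(5:15, 1))),
    character(1)))
  names(recs) <- paste0("r", 1:4)
  ab <- progressiveMsa(recs)
  m <- do.call(rbind, strsplit(as.character(ab), ""))
  blockCols <- vapply(seq_len(ncol(m) - nchar(block) + 1L), function(j)
    all(apply(m[, j:(j + nchar(block) - 1L), drop = FALSE], 1, paste,
              collapse = "") == block), logical(1))
  expect_true(any(blockCols))
  expect_error(progressiveMsa(same[1]), "at least 2")
})

test_that("p-distance uses pairwise deletion and matches a column-count oracle", {
  aln <- Biostrings::AAStringSet(c(a = "AAAAAAAAAA", b = "AAAAAAAAAC"))
  expect_equal(pdistance(aln)["a", "b"], 0.1)
  expect_equal(pdistance(Biostrings::AAStringSet(c(x = "MKLV", y = "MKLV")))["x", "y"], 0)

  set.seed(37)
  letters20 <- c("A", "C", "D", "-")
  for (i in 1:10) {
    m <- matrix(sample(letters20, 3 * 30, replace = TRUE, prob = c(.3, .3, .3, .1)),
                3, 30, dimnames = list(c("a", "b", "c"), NULL))
    D <- pdistance(m)
    for (p in list(c(1, 2), c(1, 3), c(2, 3))) {
      ok <- m[p[1], ] != "-" & m[p[2], ] != "-"
      expect_equal(D[p[1], p[2]], sum(m[p[1], ok] != m[p[2], ok]) / sum(ok))
    }
  }
  expect_error(pdistance(matrix(c("A", "-", "-", "A"), 2, 2,
                                dimnames = list(c("a", "b"), NULL))),
               "comparable")
})

test_that("NJ solves the three-taxon closed form and rejects bad input", {
  D <- matrix(c(0, 4, 6, 4, 0, 8, 6, 8, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- njTree(D)
  # closed form: va = (dab + dac - dbc)/2 = 1, vb = 3, vc = 5
  lens <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(lens[c("a", "b", "c")]), c(1, 3, 5))
  bad <- D; bad[1, 2] <- 5
  expect_error(njTree(bad), "symmetric")
  expect_error(njTree(D[1:2, 1:2]), "at least 3")
})

test_that("NJ exactly recovers additive trees (4 and 5 taxa)", {
  set.seed(43)
  for (rep in 1:10) {
    ntax <- sample(4:5, 1)
    tr0 <- ape::rtree(ntax, rooted = FALSE,
                      tip.label = paste0("t", seq_len(ntax)))
    tr0$edge.length <- stats::runif(nrow(tr0$edge), 0.5, 3)
    D <- tree_distance(tr0)
    D <- D[sort(rownames(D)), sort(rownames(D))]
    got <- njTree(D)
    expect_true(same_topology(got, tr0))
    # path-length matrix reproduced to 1e-9 (additivity)
    P <- ape::cophenetic.phylo(got)[rownames(D), colnames(D)]
    expect_equal(P, D, tolerance = 1e-9)
  }
})

test_that("NJ topology matches the independent ape implementation on random matrices", {
  set.seed(47)
  for (rep in 1:20) {
    n <- 5
    M <- matrix(stats::runif(n * n, 0.1, 1), n, n)
    D <- (M + t(M)) / 2; diag(D) <- 0
    dimnames(D) <- list(paste0("x", 1:n), paste0("x", 1:n))
    expect_true(same_topology(njTree(D), ape::nj(D)))
  }
})

test_that("NJ on ultrametric distances matches UPGMA topology", {
  set.seed(53)
  for (rep in 1:5) {
    tr0 <- ape::rcoal(6, tip.label = paste0("u", 1:6))
    D <- tree_distance(tr0)
    upgma <- ape::as.phylo(stats::hclust(stats::as.dist(D), "average"))
    expect_true(same_topology(njTree(D), upgma))
  }
})

test_that("bootstrap supports are deterministic and strong for planted clades", {
  # two clearly separated clades of 3
  set.seed(59)
  cladeA <- rand_protein(120)
  cladeB <- rand_protein(120)
  mut <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(seq_along(ch), k)
    ch[pos] <- sample(c("A", "G", "S", "T"), k, replace = TRUE)
    paste(ch, collapse = "")
  }
  recs <- Biostrings::AAStringSet(c(
    a1 = mut(cladeA, 3), a2 = mut(cladeA, 3), a3 = mut(cladeA, 3),
    b1 = mut(cladeB, 3), b2 = mut(cladeB, 3), b3 = mut(cladeB, 3)))
  aln <- progressiveMsa(recs)
  t1 <- bootstrapTree(aln, n = 100, seed = 11)
  t2 <- bootstrapTree(aln, n = 100, seed = 11)
  expect_identical(writeNewick(t1), writeNewick(t2))
  supp <- suppressWarnings(as.numeric(t1$node.label))
  supp <- supp[!is.na(supp)]
  # the a-clade and b-clade bipartition is strongly supported
  expect_true(any(supp >= 95))
  expect_true(all(supp >= 0 & supp <= 100))

  # identical sequences: tie-broken topology is stable, all supports 100
  same <- Biostrings::AAStringSet(stats::setNames(rep("MKLVWRKY", 4),
                                                  paste0("s", 1:4)))
  ts <- bootstrapTree(same, n = 20, seed = 3)
  ssupp <- suppressWarnings(as.numeric(ts$node.label))
  expect_true(all(ssupp[!is.na(ssupp)] == 100))
  expect_error(bootstrapTree(aln, n = 0), ">= 1")
})

test_that("bootstrap supports are invariant under leaf relabeling", {
  set.seed(61)
  recs <- Biostrings::AAStringSet(stats::setNames(
    vapply(1:5, function(i) rand_protein(60), character(1)),
    paste0("L", 1:5)))
  aln <- progressiveMsa(recs)
  t1 <- bootstrapTree(aln, n = 50, seed = 9)
  perm <- c(L1 = "Z4", L2 = "Z1", L3 = "Z5", L4 = "Z2", L5 = "Z3")
  aln2 <- aln
  names(aln2) <- unname(perm[names(aln)])
  t2 <- bootstrapTree(aln2, n = 50, seed = 9)
  # compare supports keyed by bipartition content after renaming back
  t2$tip.label <- names(perm)[match(t2$tip.label, perm)]
  k1 <- wrkymine:::bipartition_keys(t1, sort(t1$tip.label))
  k2 <- wrkymine:::bipartition_keys(t2, sort(t2$tip.label))
  s1 <- stats::setNames(t1$node.label, k1)
  s2 <- stats::setNames(t2$node.label, k2)
  common <- intersect(names(s1), names(s2))
  expect_true(length(common) >= 2)
  expect_identical(s1[common], s2[common])
})
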