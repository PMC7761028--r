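# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths.

IUPAC_RX <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
              S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
              D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")

iupac_to_regex <- function(pat) {
  paste(IUPAC_RX[strsplit(pat, "")[[1L]]], collapse = "")
}

revcomp_chr <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(x, "")[[1L]]]), collapse = "")
}

# overlapping regex match starts (1-based)
regex_starts <- function(x, rx) {
  m <- gregexpr(paste0("(?=", rx, ")"), x, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer() else as.integer(m)
}

# brute-force promoter scan: data.frame(motif, strand, start) per strand mode
oracle_scan <- function(seq, motifs, strandMode = "forward") {
  rows <- list()
  for (nm in names(motifs)) for (pat in motifs[[nm]]) {
    w <- nchar(pat)
    for (s in regex_starts(seq, iupac_to_regex(pat)))
      rows[[length(rows) + 1L]] <- data.frame(motif = nm, strand = "+",
                                              start = s, end = s + w - 1L)
    if (strandMode == "both") {
      for (s in regex_starts(seq, iupac_to_regex(revcomp_chr(pat))))
        rows[[length(rows) + 1L]] <- data.frame(motif = nm, strand = "-",
                                                start = s, end = s + w - 1L)
    }
  }
  if (!length(rows))
    return(data.frame(motif = character(), strand = character(),
                      start = integer(), end = integer()))
  h <- do.call(rbind, rows)
  if (strandMode == "both") {
    h <- h[order(h$motif, h$start, h$strand), ]
    h <- h[!duplicated(paste(h$motif, h$start, h$end)), ]
  }
  h[order(h$motif, h$start, h$strand), ]
}

# exhaustive-enumeration global affine alignment score (front recursion,
# no dynamic programming table shared with the implementation)
oracle_align_score <- function(a, b, sub, go, ge) {
  ca <- strsplit(a, "")[[1L]]; cb <- strsplit(b, "")[[1L]]
  n <- length(ca); m <- length(cb)
  rec <- function(i, j, last) {
    if (i > n && j > m) return(0)
    if (i > n)
      return((if (last == "l") ge else go) + ge * (m - j) )
    if (j > m)
      return((if (last == "u") ge else go) + ge * (n - i))
    best <- sub[ca[i], cb[j]] + rec(i + 1L, j + 1L, "d")
    up <- (if (last == "u") ge else go) + rec(i + 1L, j, "u")
    lf <- (if (last == "l") ge else go) + rec(i, j + 1L, "l")
    max(best, up, lf)
  }
  rec(1L, 1L, "d")
}

# random protein string over the full 20-letter alphabet
rand_protein <- function(n) {
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

rand_dna <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE),
                              collapse = "")

# additive distance matrix from an ape tree (independent of pdistance/nj)
tree_distance <- function(tree) ape::cophenetic.phylo(tree)

# unrooted topology equality
same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}
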