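AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

expand_moves <- function(a, b, moves) {
  ca <- strsplit(a, "")[[1L]]; cb <- strsplit(b, "")[[1L]]
  ia <- 0L; ib <- 0L
  oa <- character(length(moves)); ob <- character(length(moves))
  for (k in seq_along(moves)) {
    m <- moves[k]
    if (m == 1L) { ia <- ia + 1L; ib <- ib + 1L; oa[k] <- ca[ia]; ob[k] <- cb[ib] }
    else if (m == 2L) { ia <- ia + 1L; oa[k] <- ca[ia]; ob[k] <- "-" }
    else { ib <- ib + 1L; oa[k] <- "-"; ob[k] <- cb[ib] }
  }
  c(paste(oa, collapse = ""), paste(ob, collapse = ""))
}

#' Optimal global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch alignment under an affine gap model: a gap of length L
#' costs \code{gapOpen + (L - 1) * gapExtend}.  Traceback is deterministic,
#' preferring diagonal over up (gap in \code{b}) over left on ties.
#'
#' @param a,b sequences (character scalars or \linkS4class{XString}).
#' @param substitutionMatrix a named square score matrix; default BLOSUM62.
#' @param gapOpen,gapExtend gap penalties (negative).
#' @return list with \code{a}, \code{b} (aligned strings), \code{score}, and
#'   \code{identity} (matched-column fraction over alignment columns where
#'   both sequences have residues).
#' @examples
#' pairwiseGlobalAlign("WRKYGQK", "WRKYGKK")$identity
#' @export
pairwiseGlobalAlign <- function(a, b, substitutionMatrix = blosum62(),
                                gapOpen = -10, gapExtend = -1) {
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  ca <- strsplit(a, "")[[1L]]; cb <- strsplit(b, "")[[1L]]
  bad <- setdiff(c(ca, cb), rownames(substitutionMatrix))
  if (length(bad)) stop("letters not in substitution matrix: ",
                        paste(unique(bad), collapse = ", "))
  S <- substitutionMatrix[ca, cb, drop = FALSE]
  res <- .nwAffine(matrix(as.numeric(S), nrow = length(ca)), gapOpen, gapExtend)
  al <- expand_moves(a, b, res$moves)
  c1 <- strsplit(al[1], "")[[1L]]; c2 <- strsplit(al[2], "")[[1L]]
  both <- c1 != "-" & c2 != "-"
  list(a = al[1], b = al[2], score = res$score,
       identity = if (any(both)) mean(c1[both] == c2[both]) else 0)
}

# alignment as character matrix (rows = records)
aln_matrix <- function(aln) {
  do.call(rbind, strsplit(as.character(aln), ""))
}

# 20 x ncol residue-frequency profile of an alignment block; columns are
# weighted by occupancy (gaps contribute zero mass), so conserved occupied
# columns dominate the profile-profile score
profile_freq <- function(mat) {
  apply(mat, 2L, function(col) {
    tb <- table(factor(col[col != "-"], levels = AA20))
    as.numeric(tb) / nrow(mat)
  })
}

merge_profiles <- function(m1, m2, subMat, gapOpen, gapExtend) {
  M <- subMat[AA20, AA20]
  f1 <- profile_freq(m1); f2 <- profile_freq(m2)
  S <- t(f1) %*% M %*% f2
  res <- .nwAffine(S, gapOpen, gapExtend)
  n1 <- ncol(m1); n2 <- ncol(m2)
  i <- 0L; j <- 0L
  cols1 <- integer(0); cols2 <- integer(0)  # 0 = gap column
  for (m in res$moves) {
    if (m == 1L) { i <- i + 1L; j <- j + 1L; cols1 <- c(cols1, i); cols2 <- c(cols2, j) }
    else if (m == 2L) { i <- i + 1L; cols1 <- c(cols1, i); cols2 <- c(cols2, 0L) }
    else { j <- j + 1L; cols1 <- c(cols1, 0L); cols2 <- c(cols2, j) }
  }
  take <- function(mat, cols) {
    out <- matrix("-", nrow = nrow(mat), ncol = length(cols))
    nz <- cols != 0L
    out[, nz] <- mat[, cols[nz], drop = FALSE]
    out
  }
  rbind(take(m1, cols1), take(m2, cols2))
}

kmer_counts <- function(x, k = 3L) {
  n <- nchar(x)
  if (n < k) return(table(character()))
  table(substring(x, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
}

#' Progressive multiple sequence alignment
#'
#' A native progressive aligner: a UPGMA guide tree from k-mer (k = 3)
#' distances, then profile-profile global alignment with affine gaps along
#' the guide tree.  Intended for moderately sized protein families; an
#' externally produced aligned FASTA can be used anywhere an alignment is
#' accepted.
#'
#' @param records an \linkS4class{AAStringSet} (>= 2 records).
#' @param substitutionMatrix,gapOpen,gapExtend see [pairwiseGlobalAlign()].
#' @return An \linkS4class{AAStringSet} of equal-width aligned sequences in
#'   input order.
#' @export
progressiveMsa <- function(records, substitutionMatrix = blosum62(),
                           gapOpen = -10, gapExtend = -1) {
  stopifnot(is(records, "AAStringSet"))
  n <- length(records)
  if (n < 2L) stop("need at least 2 records")
  seqs <- as.character(records)
  k <- 3L
  counts <- lapply(seqs, kmer_counts, k = k)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ci <- counts[[i]]; cj <- counts[[j]]
    common <- intersect(names(ci), names(cj))
    shared <- sum(pmin(as.integer(ci[common]), as.integer(cj[common])))
    denom <- min(sum(ci), sum(cj))
    D[i, j] <- D[j, i] <- if (denom > 0) 1 - shared / denom else 1
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  blocks <- lapply(seqs, function(s) matrix(strsplit(s, "")[[1L]], nrow = 1L))
  rows <- as.list(seq_len(n))
  merged <- vector("list", n - 1L)
  mergedRows <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    pick <- function(idx) if (idx < 0) list(blocks[[-idx]], rows[[-idx]])
                          else list(merged[[idx]], mergedRows[[idx]])
    a <- pick(hc$merge[s, 1L]); b <- pick(hc$merge[s, 2L])
    merged[[s]] <- merge_profiles(a[[1L]], b[[1L]], substitutionMatrix,
                                  gapOpen, gapExtend)
    mergedRows[[s]] <- c(a[[2L]], b[[2L]])
  }
  final <- merged[[n - 1L]]
  ord <- order(mergedRows[[n - 1L]])
  out <- Biostrings::AAStringSet(apply(final[ord, , drop = FALSE], 1L,
                                       paste, collapse = ""))
  names(out) <- names(records)
  out
}

#' Pairwise p-distances from an alignment
#'
#' Mismatch proportion per pair over columns where neither sequence has a
#' gap (pairwise deletion).  The optional Kimura correction for proteins is
#' \code{d = -log(1 - p - p^2/5)}.
#'
#' @param alignment equal-width \linkS4class{AAStringSet} (gaps as '-').
#' @param correction \code{"none"} (default) or \code{"kimura"}.
#' @return symmetric numeric matrix with zero diagonal, labeled by record.
#' @export
pdistance <- function(alignment, correction = c("none", "kimura")) {
  correction <- match.arg(correction)
  if (is(alignment, "XStringSet")) {
    stopifnot(length(unique(Biostrings::width(alignment))) == 1L)
    mat <- aln_matrix(alignment)
    rownames(mat) <- names(alignment)
  } else mat <- alignment
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- mat[i, ] != "-" & mat[j, ] != "-"
    if (!any(ok)) stop("no comparable columns between records ", i, " and ", j)
    p <- mean(mat[i, ok] != mat[j, ok])
    d <- if (correction == "kimura") {
      arg <- 1 - p - p^2 / 5
      if (arg <= 0) stop("p-distance too large for Kimura correction") else -log(arg)
    } else p
    D[i, j] <- D[j, i] <- d
  }
  D
}
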