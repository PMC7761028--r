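fmt_len <- function(x) sprintf("%.12g", max(x, 0))

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the Studier-Keppler Q criterion.  Ties on Q
#' are broken deterministically toward the pair whose canonical labels (the
#' alphabetically smallest leaf label inside each cluster) sort first.
#' Negative branch lengths are clamped to zero with the deficit transferred
#' to the sibling branch, so path lengths between the joined pair are
#' preserved.  The result is unrooted, represented with a trifurcating root.
#'
#' @param D symmetric numeric matrix with labels and zero diagonal (>= 3).
#' @return an \code{ape} \code{phylo} object.
#' @examples
#' D <- matrix(c(0, 5, 9, 9, 5, 0, 10, 10, 9, 10, 0, 8, 9, 10, 8, 0), 4, 4,
#'             dimnames = list(letters[1:4], letters[1:4]))
#' njTree(D)
#' @export
njTree <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be square")
  if (max(abs(D - t(D))) > 1e-12) stop("D must be symmetric")
  labs <- rownames(D)
  if (is.null(labs)) stop("D must have row labels")
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 taxa")
  newick <- labs          # growing subtree strings
  canon <- labs           # canonical (smallest contained leaf) labels
  d <- D
  while (nrow(d) > 3L) {
    r <- nrow(d)
    R <- rowSums(d)
    Q <- (r - 2) * d - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1L, function(ij) {
      p <- sort(c(canon[ij[1]], canon[ij[2]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(key)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    vi <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    vj <- d[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    nodeStr <- sprintf("(%s:%s,%s:%s)", newick[i], fmt_len(vi),
                       newick[j], fmt_len(vj))
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    newC <- min(canon[i], canon[j])
    canon <- c(canon[keep], newC)
    newick <- c(newick[keep], nodeStr)
    dimnames(d2) <- list(canon, canon)
    d <- d2
  }
  if (nrow(d) == 3L) {
    va <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
    vb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
    vc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
    txt <- sprintf("(%s:%s,%s:%s,%s:%s);", newick[1], fmt_len(va),
                   newick[2], fmt_len(vb), newick[3], fmt_len(vc))
  }
  ape::read.tree(text = txt)
}

# canonical bipartition keys for every internal edge of an unrooted tree.
# each key is the sorted label set of the side NOT containing the reference
# label (the alphabetically first tip of `allLabs`)
bipartition_keys <- function(tree, allLabs) {
  pp <- ape::prop.part(tree)
  tipLabs <- attr(pp, "labels")
  ref <- sort(allLabs)[1L]
  keys <- vapply(pp, function(ix) {
    side <- tipLabs[ix]
    if (ref %in% side) side <- setdiff(allLabs, side)
    paste(sort(side), collapse = "\r")
  }, character(1))
  keys
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the full-data NJ tree, then resamples alignment columns with
#' replacement \code{n} times; the support of each internal bipartition of
#' the full-data tree is the percentage of replicate trees containing it.
#' Fully reproducible for a fixed \code{seed}.
#'
#' @param alignment equal-width \linkS4class{AAStringSet}.
#' @param n number of bootstrap replicates (default 1000).
#' @param seed integer seed driving the column resampling.
#' @param correction passed to [pdistance()].
#' @return an \code{ape} \code{phylo} with integer percentage supports in
#'   \code{node.label} (root label empty).
#' @export
bootstrapTree <- function(alignment, n = 1000L, seed = 1L,
                          correction = "none") {
  if (n < 1L) stop("n must be >= 1")
  mat <- aln_matrix(alignment)
  rownames(mat) <- names(alignment)
  ref <- njTree(pdistance(mat, correction))
  labs <- sort(ref$tip.label)
  refKeys <- bipartition_keys(ref, labs)
  hits <- integer(length(refKeys))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  nc <- ncol(mat)
  for (b in seq_len(n)) {
    cols <- sample.int(nc, nc, replace = TRUE)
    dB <- pdistance(mat[, cols, drop = FALSE], correction)
    tB <- njTree(dB)
    hits <- hits + as.integer(refKeys %in% bipartition_keys(tB, labs))
  }
  supp <- round(100 * hits / n)
  lab <- as.character(supp)
  lab[1L] <- ""   # root pseudo-bipartition
  ref$node.label <- lab
  ref
}
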