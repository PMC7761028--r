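as_protein_string <- function(seq) {
  if (is(seq, "AAString") || is(seq, "AAStringSet")) {
    if (is(seq, "AAStringSet")) {
      stopifnot(length(seq) == 1L)
      seq <- seq[[1L]]
    }
    return(as.character(seq))
  }
  if (is.character(seq) && length(seq) == 1L) return(seq)
  if (is(seq, "DNAString") || is(seq, "DNAStringSet"))
    stop("DNA input; protein sequence required")
  stop("unsupported sequence type")
}

# all (overlapping) match starts of a fixed-width pattern, 1-based
overlapping_starts <- function(x, pattern) {
  m <- gregexpr(paste0("(?=", pattern, ")"), x, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer() else as.integer(m)
}

# try to anchor a zinc-finger motif at position `at`; returns the four
# coordinating-residue positions or NULL
match_zf_at <- function(x, at, x1, x2, last) {
  pat <- sprintf("^(C)(.{%d,%d})(C)(.{%d,%d})(H)(.)(%s)",
                 x1[1], x1[2], x2[1], x2[2], last)
  sub <- substring(x, at)
  m <- regexpr(pat, sub, perl = TRUE)
  if (m == -1L) return(NULL)
  len <- attr(m, "capture.length")
  # cumulative offsets of the 7 capture groups
  starts <- at + c(0L, cumsum(len))[1:7]
  starts[c(1L, 3L, 5L, 7L)]
}

#' Locate WRKY domains in a protein sequence
#'
#' Finds every occurrence of the conserved heptapeptide (all overlapping
#' matches are reported) and, for each, attaches the nearest downstream
#' zinc-finger motif whose first coordinating cysteine lies within
#' \code{maxGap} residues of the heptapeptide end.  The finger is classed
#' C2H2 when its fourth coordinating residue is histidine and C2HC when it
#' is cysteine, each with its own spacing windows (see
#' [wrkyPattern()]).  A hit is \emph{complete} when both the heptapeptide
#' and a zinc finger are present.
#'
#' @param seq a protein sequence (\linkS4class{AAString}, single-record
#'   \linkS4class{AAStringSet}, or character scalar).
#' @param pattern a [WrkyPattern-class]; defaults to [wrkyPattern()].
#' @return data.frame with one row per heptapeptide occurrence: columns
#'   \code{hepta_start}, \code{hepta_end} (1-based inclusive),
#'   \code{hepta_seq}, \code{zf_class} (\code{"C2H2"}, \code{"C2HC"} or
#'   \code{"none"}), \code{zf_pos} (comma-separated coordinating-residue
#'   positions or \code{NA}), \code{complete}.
#' @examples
#' s <- paste0(strrep("M", 5), "WRKYGQK", strrep("A", 3), "C", strrep("A", 5),
#'             "C", strrep("A", 23), "H", "A", "H", strrep("A", 5))
#' findWrkyDomains(s)
#' @export
findWrkyDomains <- function(seq, pattern = wrkyPattern()) {
  x <- as_protein_string(seq)
  stopifnot(is(pattern, "WrkyPattern"))
  starts <- sort(unique(unlist(lapply(pattern@heptapeptides, function(p)
    overlapping_starts(x, p)))))
  empty <- data.frame(hepta_start = integer(), hepta_end = integer(),
                      hepta_seq = character(), zf_class = character(),
                      zf_pos = character(), complete = logical(),
                      stringsAsFactors = FALSE)
  if (!length(starts)) return(empty)
  rows <- lapply(starts, function(s) {
    hend <- s + 6L
    zf_class <- "none"; zf_pos <- NA_character_
    # candidate cysteines in the allowed gap window, nearest first
    lim <- min(nchar(x), hend + pattern@maxGap + 1L)
    if (hend < nchar(x)) {
      win <- substring(x, hend + 1L, lim)
      cpos <- hend + overlapping_starts(win, "C")
      for (at in cpos) {
        hit <- match_zf_at(x, at, pattern@c2h2X1, pattern@c2h2X2, "H")
        if (!is.null(hit)) { zf_class <- "C2H2" }
        else {
          hit <- match_zf_at(x, at, pattern@c2hcX1, pattern@c2hcX2, "C")
          if (!is.null(hit)) zf_class <- "C2HC"
        }
        if (!is.null(hit)) { zf_pos <- paste(hit, collapse = ","); break }
      }
    }
    data.frame(hepta_start = s, hepta_end = hend,
               hepta_seq = substring(x, s, hend),
               zf_class = zf_class, zf_pos = zf_pos,
               complete = zf_class != "none", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Locate a leucine-zipper heptad repeat
#'
#' Reports the first window holding at least four leucines at exact period
#' seven (L-X6-L-X6-L-X6-L), the minimal heptad signature of a dimerization
#' zipper.
#'
#' @param seq protein sequence (see [findWrkyDomains()]).
#' @return integer vector \code{c(start, end)} (1-based inclusive, spanning
#'   the first four periods) or \code{NULL} when absent.
#' @export
findLeucineZipper <- function(seq) {
  x <- as_protein_string(seq)
  n <- nchar(x)
  ch <- strsplit(x, "")[[1L]]
  isL <- ch == "L"
  for (i in seq_len(max(0L, n - 21L))) {
    if (isL[i] && isL[i + 7L] && isL[i + 14L] && isL[i + 21L])
      return(c(start = i, end = i + 21L))
  }
  NULL
}

#' Locate candidate nuclear localization signals
#'
#' Heuristic: every length-10 window containing at least four basic residues
#' (K or R) qualifies; overlapping qualifying windows are merged into
#' maximal intervals.  This declared rule detects classical basic-patch
#' signals such as SSRKRKLESP.
#'
#' @param seq protein sequence (see [findWrkyDomains()]).
#' @return data.frame with columns \code{start}, \code{end} (1-based
#'   inclusive); zero rows when nothing qualifies.
#' @export
findNls <- function(seq) {
  x <- as_protein_string(seq)
  n <- nchar(x)
  empty <- data.frame(start = integer(), end = integer())
  if (n < 10L) return(empty)
  basic <- as.integer(strsplit(x, "")[[1L]] %in% c("K", "R"))
  cs <- c(0L, cumsum(basic))
  starts <- seq_len(n - 9L)
  ok <- (cs[starts + 10L] - cs[starts]) >= 4L
  if (!any(ok)) return(empty)
  qs <- starts[ok]
  # merge overlapping windows [s, s+9]
  brk <- c(TRUE, diff(qs) > 10L)
  grp <- cumsum(brk)
  do.call(rbind, lapply(split(qs, grp), function(g)
    data.frame(start = min(g), end = max(g) + 9L)))
}

#' Annotate a whole proteome for WRKY features
#'
#' @param proteome an \linkS4class{AAStringSet}.
#' @param pattern a [WrkyPattern-class].
#' @return data.frame of domain hits over all proteins, with a leading
#'   \code{protein_id} column (proteins without hits contribute no rows).
#' @export
scanProteome <- function(proteome, pattern = wrkyPattern()) {
  stopifnot(is(proteome, "AAStringSet"))
  res <- lapply(names(proteome), function(id) {
    h <- findWrkyDomains(as.character(proteome[[id]]), pattern)
    if (nrow(h)) cbind(protein_id = id, h, stringsAsFactors = FALSE) else NULL
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res))
    return(data.frame(protein_id = character(), hepta_start = integer(),
                      hepta_end = integer(), hepta_seq = character(),
                      zf_class = character(), zf_pos = character(),
                      complete = logical(), stringsAsFactors = FALSE))
  do.call(rbind, res)
}
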