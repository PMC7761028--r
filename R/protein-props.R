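#' Average residue mass table (Da)
#'
#' Average (isotope-abundance-weighted) residue masses of the 20 standard
#' amino acids; a peptide's mass is the residue sum plus one water
#' (18.0153 Da).
#'
#' @return named numeric vector of residue masses plus element
#'   \code{water}.
#' @export
massTable <- function() {
  c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
    E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
    L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
    S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326,
    water = 18.0153)
}

#' Bjellqvist pKa table
#'
#' The pKa set behind the common theoretical-pI calculators: free termini
#' plus the ionizable side chains D, E, C, Y, H, K, R.
#'
#' @return named numeric vector with elements \code{Nterm}, \code{Cterm},
#'   \code{D}, \code{E}, \code{C}, \code{Y}, \code{H}, \code{K}, \code{R}.
#' @export
pkaTable <- function() {
  c(Nterm = 7.5, Cterm = 3.55,
    D = 4.05, E = 4.45, C = 9.0, Y = 10.0, H = 5.98, K = 10.0, R = 12.0)
}

check_protein_letters <- function(seq, skipX = FALSE) {
  if (!nzchar(seq)) stop("empty sequence")
  ch <- strsplit(seq, "")[[1L]]
  if (skipX) ch <- ch[ch != "X"]
  bad <- setdiff(ch, AA20)
  if (length(bad))
    stop("non-standard residue(s): ", paste(unique(bad), collapse = ", "))
  ch
}

#' Theoretical molecular weight of a protein
#'
#' Sum of average residue masses plus one water.
#'
#' @param seq protein sequence (character scalar or \linkS4class{AAString}).
#' @param skipX drop unknown residues 'X' instead of erroring.
#' @return mass in Daltons.
#' @examples
#' molecularWeight("G")   # glycine residue + water
#' @export
molecularWeight <- function(seq, skipX = FALSE) {
  seq <- as.character(seq)
  ch <- check_protein_letters(seq, skipX)
  mt <- massTable()
  sum(mt[ch]) + mt[["water"]]
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over ionizable groups: each basic group
#' (N-terminus, K, R, H) contributes \code{1/(1 + 10^(pH - pKa))}; each
#' acidic group (C-terminus, D, E, C, Y) contributes
#' \code{-1/(1 + 10^(pKa - pH))}.
#'
#' @param seq protein sequence.
#' @param pH pH in [0, 14].
#' @param pka pKa table (see [pkaTable()]).
#' @param includeTermini count the free termini (default TRUE).
#' @return signed net charge.
#' @export
netCharge <- function(seq, pH, pka = pkaTable(), includeTermini = TRUE) {
  if (pH < 0 || pH > 14) stop("pH outside [0, 14]")
  seq <- as.character(seq)
  ch <- check_protein_letters(seq, skipX = TRUE)
  pos <- function(pKa) 1 / (1 + 10^(pH - pKa))
  neg <- function(pKa) -1 / (1 + 10^(pKa - pH))
  q <- 0
  if (includeTermini) q <- pos(pka[["Nterm"]]) + neg(pka[["Cterm"]])
  for (r in c("K", "R", "H")) q <- q + sum(ch == r) * pos(pka[[r]])
  for (r in c("D", "E", "C", "Y")) q <- q + sum(ch == r) * neg(pka[[r]])
  q
}

#' Theoretical isoelectric point
#'
#' Bisection on [netCharge()] over pH 0-14 until the residual charge is
#' below \code{1e-4} in magnitude.
#'
#' @param seq protein sequence.
#' @param pka pKa table.
#' @param includeTermini count the free termini.
#' @param digits decimals to round the reported pI to (default 2;
#'   \code{NULL} for full precision).
#' @return the pH of zero net charge.
#' @examples
#' isoelectricPoint("SSRKRKLESP")
#' @export
isoelectricPoint <- function(seq, pka = pkaTable(), includeTermini = TRUE,
                             digits = 2) {
  seq <- as.character(seq)
  ch <- check_protein_letters(seq, skipX = TRUE)
  ionizable <- includeTermini ||
    any(ch %in% c("D", "E", "C", "Y", "H", "K", "R"))
  if (!ionizable) stop("no ionizable groups")
  lo <- 0; hi <- 14
  f <- function(p) netCharge(seq, p, pka, includeTermini)
  for (i in seq_len(200L)) {
    mid <- (lo + hi) / 2
    q <- f(mid)
    if (abs(q) < 1e-4) break
    if (q > 0) lo <- mid else hi <- mid
  }
  if (is.null(digits)) mid else round(mid, digits)
}

#' Tabulate physico-chemical properties of a protein set
#'
#' @param proteome an \linkS4class{AAStringSet}.
#' @param skipX drop unknown residues 'X'.
#' @return data.frame: id, length, mw (Da), pi.
#' @export
proteinProperties <- function(proteome, skipX = TRUE) {
  stopifnot(is(proteome, "AAStringSet"))
  data.frame(
    id = names(proteome),
    length = Biostrings::width(proteome),
    mw = vapply(as.character(proteome), molecularWeight, numeric(1),
                skipX = skipX, USE.NAMES = FALSE),
    pi = vapply(as.character(proteome), isoelectricPoint, numeric(1),
                USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}
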