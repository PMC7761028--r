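DNA4 <- c("A", "C", "G", "T")

motif_alphabet <- function(seqs) {
  letters_seen <- unique(strsplit(paste(seqs, collapse = ""), "")[[1L]])
  if (all(letters_seen %in% c(DNA4, "N", "X"))) DNA4 else AA20
}

encode_seqs <- function(seqs, alphabet) {
  lapply(strsplit(seqs, ""), function(ch) match(ch, alphabet))  # NA = masked
}

#' Zero-order background frequencies
#'
#' @param seqs character vector of sequences.
#' @param alphabet letter set; guessed from content when NULL.
#' @param pseudocount added per letter before normalization.
#' @return named numeric vector of frequencies summing to 1, all > 0.
#' @export
backgroundFrequencies <- function(seqs, alphabet = NULL, pseudocount = 0.1) {
  if (is.null(alphabet)) alphabet <- motif_alphabet(seqs)
  ch <- strsplit(paste(seqs, collapse = ""), "")[[1L]]
  tb <- table(factor(ch[ch %in% alphabet], levels = alphabet))
  f <- as.numeric(tb) + pseudocount
  stats::setNames(f / sum(f), alphabet)
}

# log-likelihood-ratio scores of all width-w windows of one encoded sequence
window_scores <- function(code, logOdds, w) {
  L <- length(code)
  nwin <- L - w + 1L
  if (nwin < 1L) return(numeric())
  idx <- outer(seq_len(nwin), 0:(w - 1L), "+")
  v <- code[as.vector(idx)]
  sc <- matrix(logOdds[cbind(v, rep(seq_len(w), each = nwin))], nwin, w)
  out <- rowSums(sc)
  out[is.na(out)] <- -Inf    # windows overlapping masked positions
  out
}

zoops_em <- function(codes, w, theta0, bg, pseudocount = 0.1,
                     tol = 1e-4, maxIter = 100L, trace = FALSE) {
  A <- length(bg)
  gamma <- 0.5
  theta <- theta0
  llOld <- -Inf
  llTrace <- numeric()
  nwin <- vapply(codes, function(cd) max(0L, length(cd) - w + 1L), integer(1))
  use <- which(nwin > 0L)
  for (iter in seq_len(maxIter)) {
    logOdds <- log(theta) - matrix(log(bg), A, w)
    counts <- matrix(0, A, w)
    Qsum <- 0
    ll <- 0
    zlist <- vector("list", length(codes))
    for (i in use) {
      s <- window_scores(codes[[i]], logOdds, w)
      # posterior over {no site, site at j}
      aj <- gamma / nwin[i] * exp(s)
      tot <- (1 - gamma) + sum(aj)
      z <- aj / tot
      zlist[[i]] <- z
      Qsum <- Qsum + sum(z)
      ll <- ll + log(tot)
      # weighted letter counts
      cd <- codes[[i]]
      for (col in seq_len(w)) {
        lets <- cd[seq_along(z) + col - 1L]
        ok <- !is.na(lets) & z > 0
        if (any(ok)) {
          agg <- rowsum(z[ok], group = lets[ok])
          counts[as.integer(rownames(agg)), col] <-
            counts[as.integer(rownames(agg)), col] + agg[, 1L]
        }
      }
    }
    theta <- sweep(counts + pseudocount, 2L,
                   colSums(counts) + A * pseudocount, "/")
    gamma <- min(max(Qsum / length(use), 1e-6), 1 - 1e-6)
    llTrace <- c(llTrace, ll)
    if (is.finite(llOld) && abs(ll - llOld) < tol) break
    llOld <- ll
  }
  list(theta = theta, gamma = gamma, z = zlist, ll = ll, llTrace = llTrace,
       nwin = nwin)
}

information_content <- function(theta, bg) {
  sum(theta * (log2(theta) - matrix(log2(bg), nrow(theta), ncol(theta))))
}

consensus_of <- function(theta, alphabet) {
  paste(alphabet[apply(theta, 2L, which.max)], collapse = "")
}

#' Score a subsequence against a PWM
#'
#' Log-odds in bits: \code{sum(log2(p_pos(char) / bg(char)))}.
#'
#' @param pwm numeric matrix, alphabet x width, with rownames.
#' @param background named numeric background frequencies.
#' @param subsequence character scalar of length = PWM width.
#' @return numeric log-odds score in bits.
#' @export
scoreSite <- function(pwm, background, subsequence) {
  ch <- strsplit(subsequence, "")[[1L]]
  if (length(ch) != ncol(pwm))
    stop("subsequence length ", length(ch), " != PWM width ", ncol(pwm))
  idx <- match(ch, rownames(pwm))
  if (anyNA(idx)) stop("letter not in PWM alphabet")
  sum(log2(pwm[cbind(idx, seq_along(idx))]) - log2(background[ch]))
}

#' Discover ungapped motifs by ZOOPS expectation-maximization
#'
#' MEME-style iterative discovery: for each candidate width (scanned in
#' steps of 2 over \code{[wmin, wmax]}), EM under the ZOOPS model (zero or
#' one site per record) is started from the five most promising substring
#' seeds; the best converged model by information-content-per-column times
#' expected-site-count is kept.  Found sites are masked with a neutral
#' symbol before the next motif is sought.  Deterministic for a fixed
#' \code{seed}.
#'
#' @param records \linkS4class{AAStringSet}, \linkS4class{DNAStringSet}, or
#'   character vector (>= 2 records, at least one longer than \code{wmin}).
#' @param nmotifs maximum number of motifs (default 6).
#' @param wmin,wmax motif width bounds (defaults 6 and 50).
#' @param seed integer seed (used when thinning the candidate seed pool).
#' @param maxCandidates cap on substring seeds scored per width.
#' @return list of [MotifModel-class] objects, best first.
#' @export
discoverMotifs <- function(records, nmotifs = 6L, wmin = 6L, wmax = 50L,
                           seed = 1L, maxCandidates = 100L) {
  seqs <- as.character(records)
  if (length(seqs) < 2L) stop("need at least 2 records")
  if (all(nchar(seqs) < wmin)) stop("all records shorter than wmin")
  nms <- names(records)
  if (is.null(nms)) nms <- paste0("seq", seq_along(seqs))
  alphabet <- motif_alphabet(seqs)
  A <- length(alphabet)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  work <- seqs
  models <- list()
  widths <- as.integer(seq(wmin, min(wmax, max(nchar(seqs))), by = 2L))
  for (round in seq_len(nmotifs)) {
    codes <- encode_seqs(work, alphabet)
    bg <- backgroundFrequencies(work, alphabet)
    best <- NULL
    for (w in widths) {
      cand <- candidate_seeds(codes, w, maxCandidates)
      if (!length(cand)) next
      # rank candidate seeds by one-pass likelihood, keep top 5
      seedScore <- vapply(cand, function(cd)
        zoops_em(codes, w, seed_theta(cd, A, w), bg, maxIter = 1L)$ll,
        numeric(1))
      top <- cand[order(-seedScore)][seq_len(min(5L, length(cand)))]
      for (cd in top) {
        fit <- zoops_em(codes, w, seed_theta(cd, A, w), bg)
        esites <- sum(vapply(fit$z, sum, numeric(1)))
        sc <- information_content(fit$theta, bg) / w * esites
        if (is.null(best) || sc > best$score)
          best <- list(fit = fit, w = w, score = sc)
      }
    }
    if (is.null(best)) break
    fit <- best$fit
    w <- best$w
    rownames(fit$theta) <- alphabet
    # ZOOPS site calls: sequences whose posterior site mass exceeds 1/2
    sites <- do.call(rbind, lapply(seq_along(fit$z), function(i) {
      z <- fit$z[[i]]
      if (!length(z) || sum(z) <= 0.5) return(NULL)
      j <- which.max(z)
      data.frame(record = nms[i], offset = j,
                 site = substring(work[i], j, j + w - 1L),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(sites))
      sites <- data.frame(record = character(), offset = integer(),
                          site = character(), stringsAsFactors = FALSE)
    theta <- fit$theta
    if (nrow(sites) > 1L) {
      # phase refinement: EM can lock onto the planted signal shifted by a
      # residue or two; pick the shift maximizing information content
      ph <- refine_phase(work, sites, w, bg, alphabet, nms)
      if (ph$shift != 0L) { sites <- ph$sites; theta <- ph$theta }
    }
    models[[round]] <- new("MotifModel", pwm = theta, sites = sites,
                           ic = information_content(theta, bg),
                           consensus = consensus_of(theta, alphabet))
    if (!nrow(sites)) break
    # mask found sites so the next motif is different
    maskChar <- if (identical(alphabet, DNA4)) "N" else "X"
    for (r in seq_len(nrow(sites))) {
      i <- match(sites$record[r], nms)
      substr(work[i], sites$offset[r], sites$offset[r] + w - 1L) <-
        strrep(maskChar, w)
    }
  }
  models
}

# try site-set shifts of -3..3 residues; return the one with the highest
# information content rebuilt from hard site counts (pseudocount 0.1)
refine_phase <- function(work, sites, w, bg, alphabet, nms) {
  A <- length(alphabet)
  build <- function(st) {
    counts <- matrix(0, A, w, dimnames = list(alphabet, NULL))
    for (r in seq_len(nrow(st))) {
      ch <- strsplit(st$site[r], "")[[1L]]
      idx <- match(ch, alphabet)
      ok <- !is.na(idx)
      counts[cbind(idx[ok], seq_len(w)[ok])] <-
        counts[cbind(idx[ok], seq_len(w)[ok])] + 1
    }
    sweep(counts + 0.1, 2L, colSums(counts) + A * 0.1, "/")
  }
  best <- list(shift = 0L, sites = sites, theta = build(sites),
               ic = NA_real_)
  best$ic <- information_content(best$theta, bg)
  lens <- nchar(work)[match(sites$record, nms)]
  for (s in c(-3L, -2L, -1L, 1L, 2L, 3L)) {
    off <- sites$offset + s
    keep <- off >= 1L & off + w - 1L <= lens
    if (sum(keep) < max(2L, nrow(sites) %/% 2L)) next
    st <- sites[keep, , drop = FALSE]
    st$offset <- off[keep]
    st$site <- substring(work[match(st$record, nms)], st$offset,
                         st$offset + w - 1L)
    th <- build(st)
    ic <- information_content(th, bg) * nrow(st) / nrow(sites)
    if (ic > best$ic + 1e-9) {
      best <- list(shift = s, sites = st, theta = th, ic = ic)
    }
  }
  best
}

# deterministic pool of substring seeds (encoded windows), thinned to cap
candidate_seeds <- function(codes, w, cap) {
  all <- list()
  for (cd in codes) {
    nwin <- length(cd) - w + 1L
    if (nwin < 1L) next
    for (j in seq_len(nwin)) {
      win <- cd[j:(j + w - 1L)]
      if (!anyNA(win)) all[[length(all) + 1L]] <- win
    }
  }
  if (length(all) > cap) all <- all[sample.int(length(all), cap)]
  all
}

seed_theta <- function(win, A, w) {
  theta <- matrix((1 - 0.7) / (A - 1), A, w)
  theta[cbind(win, seq_len(w))] <- 0.7
  theta
}

#' Write motifs in MEME minimal text format
#'
#' @param models list of [MotifModel-class].
#' @param path output file.
#' @param background named frequencies to record in the header.
#' @return \code{path}, invisibly.
#' @export
writeMemeText <- function(models, path, background = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  alphabet <- rownames(models[[1L]]@pwm)
  writeLines(c("MEME version 4", "",
               paste("ALPHABET=", paste(alphabet, collapse = "")), ""), con)
  if (!is.null(background)) {
    writeLines("Background letter frequencies", con)
    writeLines(paste(names(background), sprintf("%.4f", background),
                     collapse = " "), con)
    writeLines("", con)
  }
  for (k in seq_along(models)) {
    m <- models[[k]]
    writeLines(sprintf("MOTIF %s motif_%d", m@consensus, k), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= %d w= %d nsites= %d",
      nrow(m@pwm), ncol(m@pwm), nrow(m@sites)), con)
    for (j in seq_len(ncol(m@pwm)))
      writeLines(paste(sprintf("%.6f", m@pwm[, j]), collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}
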