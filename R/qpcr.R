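check_ct_table <- function(ct) {
  need <- c("sample", "condition", "timepoint", "gene", "replicate", "ct")
  if (!all(need %in% names(ct)))
    stop("Ct table needs columns: ", paste(need, collapse = ", "))
  if (any(ct$ct <= 0)) stop("Ct values must be positive")
  invisible(ct)
}

#' Relative expression by the comparative 2^-ddCt method
#'
#' Livak quantification with amplification efficiency fixed at 2: per
#' replicate, dCt = Ct(target) - Ct(reference); ddCt subtracts the mean dCt
#' of the calibrator condition at the same timepoint; fold = 2^-ddCt.
#' Replicate folds are then summarized as mean and standard deviation per
#' (condition, timepoint).
#'
#' @param ct data.frame with columns \code{sample}, \code{condition},
#'   \code{timepoint}, \code{gene}, \code{replicate}, \code{ct}.
#' @param targetGene,referenceGene gene names in the table.
#' @param calibratorCondition the untreated/control condition whose mean
#'   expression defines fold 1.
#' @return data.frame per (condition, timepoint): \code{mean_fold},
#'   \code{sd_fold}, \code{n}, plus a \code{folds} list-column of replicate
#'   folds.
#' @export
deltaDeltaCt <- function(ct, targetGene, referenceGene, calibratorCondition) {
  check_ct_table(ct)
  tgt <- ct[ct$gene == targetGene, ]
  ref <- ct[ct$gene == referenceGene, ]
  if (!nrow(tgt)) stop("no rows for target gene ", targetGene)
  key <- function(d) paste(d$condition, d$timepoint, d$replicate, sep = "\r")
  m <- match(key(tgt), key(ref))
  if (anyNA(m)) {
    miss <- tgt[is.na(m), c("condition", "timepoint", "replicate")]
    stop("missing reference Ct for: ",
         paste(apply(miss, 1L, paste, collapse = "/"), collapse = "; "))
  }
  dct <- tgt$ct - ref$ct[m]
  grp <- paste(tgt$condition, tgt$timepoint, sep = "\r")
  calib <- tgt$condition == calibratorCondition
  if (!any(calib)) stop("no rows for calibrator condition ",
                        calibratorCondition)
  calMean <- tapply(dct[calib], tgt$timepoint[calib], mean)
  if (anyNA(match(tgt$timepoint, names(calMean))))
    stop("calibrator condition missing for some timepoint")
  ddct <- dct - unname(calMean[as.character(tgt$timepoint)])
  fold <- 2^(-ddct)
  groups <- unique(grp)
  out <- do.call(rbind, lapply(groups, function(g) {
    f <- fold[grp == g]
    parts <- strsplit(g, "\r")[[1L]]
    data.frame(condition = parts[1L], timepoint = parts[2L],
               mean_fold = mean(f), sd_fold = stats::sd(f),
               n = length(f), stringsAsFactors = FALSE)
  }))
  out$folds <- lapply(groups, function(g) fold[grp == g])
  rownames(out) <- NULL
  out
}

# compact letter display by insert-absorb over a pairwise significance matrix
letter_display <- function(groups, sigPairs) {
  letters_pool <- c(letters, LETTERS)
  cols <- list(groups)  # each element: set of groups sharing a letter
  for (p in seq_len(nrow(sigPairs))) {
    g1 <- sigPairs$g1[p]; g2 <- sigPairs$g2[p]
    newCols <- list()
    for (cl in cols) {
      if (g1 %in% cl && g2 %in% cl) {
        newCols <- c(newCols, list(setdiff(cl, g1)), list(setdiff(cl, g2)))
      } else newCols <- c(newCols, list(cl))
    }
    # absorb duplicates/subsets
    keep <- rep(TRUE, length(newCols))
    for (i in seq_along(newCols)) for (j in seq_along(newCols)) {
      if (i != j && keep[i] && keep[j] &&
          all(newCols[[i]] %in% newCols[[j]]) &&
          (length(newCols[[i]]) < length(newCols[[j]]) || i > j))
        keep[i] <- FALSE
    }
    cols <- newCols[keep]
  }
  out <- stats::setNames(rep("", length(groups)), groups)
  for (k in seq_along(cols))
    for (g in cols[[k]]) out[g] <- paste0(out[g], letters_pool[k])
  out
}

#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Standard one-way analysis of variance followed by Tukey's honest
#' significant difference test; groups sharing a letter are not
#' significantly different at \code{alpha}.
#'
#' @param values numeric response vector.
#' @param groups group labels (same length as \code{values}).
#' @param alpha significance level (default 0.05).
#' @return list with \code{F}, \code{p}, \code{tukey} (pairwise table from
#'   [stats::TukeyHSD()]), and \code{letters} (named by group).
#' @export
anovaTukey <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  tb <- table(groups)
  if (length(tb) < 2L) stop("need at least 2 groups")
  if (any(tb < 2L))
    stop("group(s) with a single replicate: ",
         paste(names(tb)[tb < 2L], collapse = ", "))
  gnames <- sort(names(tb))
  if (stats::var(values) == 0) {
    return(list(F = NaN, p = NA_real_, tukey = NULL,
                letters = stats::setNames(rep("a", length(gnames)), gnames)))
  }
  df <- data.frame(y = values, g = factor(groups, levels = gnames))
  fit <- stats::aov(y ~ g, data = df)
  an <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  pairs <- do.call(rbind, lapply(rownames(tk), function(r) {
    gg <- strsplit(r, "-", fixed = TRUE)[[1L]]
    data.frame(g1 = gg[1L], g2 = gg[2L], stringsAsFactors = FALSE)
  }))
  sig <- pairs[tk[, "p adj"] < alpha, , drop = FALSE]
  list(F = an["g", "F value"], p = an["g", "Pr(>F)"], tukey = tk,
       letters = letter_display(gnames, sig))
}
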