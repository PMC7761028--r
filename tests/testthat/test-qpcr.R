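flat_ct <- function(tgt, ref, conds, tp = "t1", reps = 3) {
  do.call(rbind, lapply(conds, function(cn)
    do.call(rbind, lapply(seq_len(reps), function(r)
      data.frame(sample = paste(cn, r), condition = cn, timepoint = tp,
                 gene = c("target", "reference"), replicate = r,
                 ct = c(tgt[[cn]], ref), stringsAsFactors = FALSE)))))
}

test_that("ddCt recovers closed-form fold changes", {
  # identical target/reference everywhere: fold 1
  ct <- flat_ct(list(control = 20, treated = 20), ref = 20,
                conds = c("control", "treated"))
  fc <- deltaDeltaCt(ct, "target", "reference", "control")
  expect_equal(fc$mean_fold, c(1, 1))
  expect_equal(fc$sd_fold, c(0, 0))

  # ddCt = -2 (treated target 2 cycles earlier) => fold 4
  ct2 <- flat_ct(list(control = 22, treated = 20), ref = 20,
                 conds = c("control", "treated"))
  fc2 <- deltaDeltaCt(ct2, "target", "reference", "control")
  expect_equal(fc2$mean_fold[fc2$condition == "treated"], 4)
  expect_equal(fc2$mean_fold[fc2$condition == "control"], 1)
})

test_that("ddCt is invariant to a constant shift of every Ct", {
  ct <- simulateCtTable(c(t1 = 5, t2 = 0.5), sd = 0.2, seed = 149)
  fc1 <- deltaDeltaCt(ct, "target", "reference", "control")
  ct$ct <- ct$ct + 3.7
  fc2 <- deltaDeltaCt(ct, "target", "reference", "control")
  expect_equal(fc1$mean_fold, fc2$mean_fold)
})

test_that("ddCt names missing reference measurements", {
  ct <- flat_ct(list(control = 20, treated = 18), ref = 20,
                conds = c("control", "treated"))
  ct <- ct[!(ct$gene == "reference" & ct$condition == "treated" &
               ct$replicate == 2), ]
  expect_error(deltaDeltaCt(ct, "target", "reference", "control"),
               "treated/t1/2")
})

test_that("simulated fold changes are recovered within 15%", {
  truth <- c(t30min = 25, t4h = 1.78, t24h = 1.5)
  ct <- simulateCtTable(truth, sd = 0.1, replicates = 3, seed = 151)
  fc <- deltaDeltaCt(ct, "target", "reference", "control")
  tr <- fc[fc$condition == "treated", ]
  got <- stats::setNames(tr$mean_fold, tr$timepoint)
  expect_true(all(abs(got[names(truth)] - truth) / truth < 0.15))
  # noise-free inversion is exact
  ct0 <- simulateCtTable(truth, sd = 0, seed = 1)
  fc0 <- deltaDeltaCt(ct0, "target", "reference", "control")
  tr0 <- fc0[fc0$condition == "treated", ]
  expect_equal(stats::setNames(tr0$mean_fold, tr0$timepoint)[names(truth)],
               truth)
})

test_that("the Ct simulator validates its arguments and is deterministic", {
  expect_error(simulateCtTable(c(t1 = -1)), "> 0")
  expect_error(simulateCtTable(c(t1 = 2), replicates = 1), "replicates")
  a <- simulateCtTable(c(t1 = 2), seed = 5)
  b <- simulateCtTable(c(t1 = 2), seed = 5)
  expect_identical(a, b)
})

test_that("ANOVA F matches the textbook formula on a hand-checkable table", {
  vals <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  grps <- rep(c("a", "b", "c"), each = 3)
  res <- anovaTukey(vals, grps)
  gm <- mean(vals)
  means <- tapply(vals, grps, mean)
  ssb <- 3 * sum((means - gm)^2)
  ssw <- sum((vals - means[grps])^2)
  Fhand <- (ssb / 2) / (ssw / 6)
  expect_equal(res$F, Fhand)
  expect_equal(res$p, stats::pf(Fhand, 2, 6, lower.tail = FALSE))
})

test_that("Tukey letters separate distant groups and join identical ones", {
  set.seed(157)
  # two groups 10 pooled SD apart: distinct letters
  v <- c(stats::rnorm(5, 0, 1), stats::rnorm(5, 10, 1))
  g <- rep(c("ctrl", "high"), each = 5)
  lt <- anovaTukey(v, g)$letters
  expect_false(lt[["ctrl"]] == lt[["high"]])

  # identical constant groups: one shared letter
  lt2 <- anovaTukey(rep(5, 6), rep(c("a", "b"), each = 3))$letters
  expect_identical(unname(lt2), c("a", "a"))

  expect_error(anovaTukey(1:4, c("a", "a", "a", "b")), "single replicate")
  expect_error(anovaTukey(1:4, rep("a", 4)), "2 groups")
})

test_that("letters agree with the multcomp compact letter display", {
  set.seed(163)
  for (i in 1:5) {
    shift <- c(0, sample(c(0, 3, 8), 2, replace = TRUE))
    v <- unlist(lapply(shift, function(s) stats::rnorm(4, s)))
    g <- rep(c("g1", "g2", "g3"), each = 4)
    mine <- anovaTukey(v, g)$letters
    df <- data.frame(y = v, g = factor(g))
    fit <- stats::aov(y ~ g, df)
    cl <- multcomp::cld(multcomp::glht(fit, multcomp::mcp(g = "Tukey")))
    ref <- cl$mcletters$Letters
    # compare the sharing structure, not the letter symbols
    share <- function(lt) outer(lt, lt, function(x, y)
      mapply(function(a, b) any(strsplit(a, "")[[1]] %in%
                                  strsplit(b, "")[[1]]), x, y))
    expect_identical(unname(share(mine[sort(names(mine))])),
                     unname(share(ref[sort(names(ref))])))
  }
})

test_that("fold-change pipeline attaches letters per timepoint", {
  ct <- simulateCtTable(c(t1 = 20, t2 = 1), sd = 0.1, seed = 167)
  fc <- runQpcr(ct)
  t1 <- fc[fc$timepoint == "t1", ]
  expect_false(t1$letter[t1$condition == "control"] ==
                 t1$letter[t1$condition == "treated"])
  t2 <- fc[fc$timepoint == "t2", ]
  expect_identical(t2$letter[1], t2$letter[2])
})
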