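test_that("concordance counts pathogenic and benign strata per their own call", {
  fx <- generateFixture(manifest = data.frame(
    source = "ClinVar", gene = "COL4A3",
    label_class = c("pathogenic", "benign"), n_total = c(16, 6),
    n_target_predicted_pathogenic = c(12, 0)), seed = 31)
  calls <- classifyCohort(fx$panels)
  rep <- concordance(calls, fx$variants)
  st <- strata(rep)
  expect_equal(st$fraction[st$label_class == "pathogenic"], 12 / 16)
  expect_equal(st$fraction[st$label_class == "benign"], 1.0)
  cf <- confusion(rep)
  expect_equal(cf$TP, 12); expect_equal(cf$FN, 4)
  expect_equal(cf$FP, 0);  expect_equal(cf$TN, 6)

})

test_that("inverting every call flips each stratum's concordance (complement)", {
  set.seed(66)
  n <- 40
  dmat <- matrix(runif(n * 12) < 0.7, nrow = n)   # full panels, no missing
  vt <- rbind(variantsFor(sprintf("v%04d", 1:20), label = "pathogenic"),
              variantsFor(sprintf("v%04d", 21:40), label = "benign"))
  calls <- classifyCohort(panelsFromVotes(dmat), REG, 10)
  calls@variantIds <- vt$variant_id
  rownames(calls@votes) <- vt$variant_id
  # flipping every vote with k' = m - k + 1 = 3 negates each call exactly
  inv <- classifyCohort(panelsFromVotes(!dmat), REG, 3)
  inv@variantIds <- vt$variant_id
  expect_identical(isPredictedPathogenic(inv),
                   !isPredictedPathogenic(calls))
  st <- strata(concordance(calls, vt))
  st2 <- strata(concordance(inv, vt))
  expect_equal(st2$fraction, 1 - st$fraction)
})

test_that("orphan variant ids are reported", {
  fx <- generateFixture(manifest = data.frame(
    source = "synthetic", gene = "COL4A3", label_class = "pathogenic",
    n_total = 3, n_target_predicted_pathogenic = 3), seed = 1)
  calls <- classifyCohort(fx$panels)
  expect_error(concordance(calls, fx$variants[-1, ]), "unresolved")
})

test_that("single-tool evaluation treats a missing output as wrong for both classes", {
  ids <- sprintf("v%02d", 1:10)
  vt <- rbind(variantsFor(ids[1:5], label = "pathogenic", source = "ClinVar"),
              variantsFor(ids[6:10], label = "benign", source = "ClinVar"))
  # M-CAP-like behavior on benign variants: deleterious or no output
  sc <- data.frame("M-CAP" = c(0.4, 0.4, NA, 0.4, 0.4,   # pathogenic
                               0.4, NA, 0.4, NA, 0.4),   # benign
                   check.names = FALSE)
  panels <- ScorePanelSet(sc, REG, ids)
  st <- strata(singleToolEval(panels, vt, "M-CAP"))
  expect_equal(st$n_concordant[st$label_class == "benign"], 0)
  expect_equal(st$fraction[st$label_class == "pathogenic"], 4 / 5)

  # a tool with no output at all is concordant with neither stratum
  none <- ScorePanelSet(data.frame("M-CAP" = rep(NA_real_, 10),
                                   check.names = FALSE), REG, ids)
  st0 <- strata(singleToolEval(none, vt, "M-CAP"))
  expect_equal(st0$n_concordant, c(0, 0))

  # a pathogenic stratum with high per-variant accuracy lands in [0.89, 0.96]
  n <- 100
  vt2 <- variantsFor(sprintf("p%03d", 1:n), label = "pathogenic",
                     source = "LOVD")
  sc2 <- data.frame("M-CAP" = c(rep(0.4, 92), rep(NA, 8)),
                    check.names = FALSE)
  st2 <- strata(singleToolEval(ScorePanelSet(sc2, REG, vt2$variant_id),
                               vt2, "M-CAP"))
  expect_gte(st2$fraction, 0.89)
  expect_lte(st2$fraction, 0.96)
})

test_that("ROC on separable classes is perfect with the cutoff between them", {
  spec <- toolSpec(REG, "SIFT")
  r <- rocCurve(c(0.001, 0.002, 0.003, 0.01, 0.2),
                c(rep("pathogenic", 3), rep("benign", 2)), spec)
  expect_equal(auc(r), 1.0)
  expect_equal(youdenJ(r), 1.0)
  expect_gt(optimalThreshold(r), 0.003)
  expect_lte(optimalThreshold(r), 0.01)
  # TPR and FPR are monotone along the sweep
  expect_true(all(diff(rocPoints(r)$tpr) >= 0))
  expect_true(all(diff(rocPoints(r)$fpr) >= 0))
  expect_error(rocCurve(1:3 / 10, rep("pathogenic", 3), spec),
               "ROC undefined")
})

test_that("missing scores are excluded from the curve and counted", {
  spec <- toolSpec(REG, "SIFT")
  r <- rocCurve(c(0.001, NA, 0.2, NA), c("pathogenic", "pathogenic",
                                         "benign", "benign"), spec)
  expect_equal(r@nMissing, 2L)
  expect_equal(auc(r), 1.0)
})

test_that("AUC equals the normalized Mann-Whitney U on random panels", {
  set.seed(202)
  spec_hi <- toolSpec(REG, "M-CAP")
  spec_lo <- toolSpec(REG, "SIFT")
  for (i in 1:200) {
    n1 <- sample(3:15, 1); n0 <- sample(3:15, 1)
    # discretized scores force ties to exercise the 1/2 convention
    pos <- round(runif(n1), sample(1:2, 1))
    neg <- round(runif(n0), sample(1:2, 1))
    labels <- c(rep("pathogenic", n1), rep("benign", n0))
    spec <- if (i %% 2) spec_hi else spec_lo
    r <- rocCurve(c(pos, neg), labels, spec)
    u <- if (spec$orientation == "higher_is_damaging")
      unname(stats::wilcox.test(pos, neg, exact = FALSE)$statistic)
    else unname(stats::wilcox.test(neg, pos, exact = FALSE)$statistic)
    expect_equal(auc(r), u / (n1 * n0), tolerance = 1e-10)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  sc <- c(rnorm(30, 0.3, 0.1), rnorm(25, 0.6, 0.15))
  labels <- c(rep("benign", 30), rep("pathogenic", 25))
  r <- rocCurve(sc, labels, toolSpec(REG, "M-CAP"))
  ref <- pROC::auc(pROC::roc(response = labels == "pathogenic",
                             predictor = sc, quiet = TRUE,
                             direction = "<"))
  expect_equal(auc(r), as.numeric(ref), tolerance = 1e-10)
})

test_that("permuted labels give chance-level AUC", {
  set.seed(55)
  sc <- runif(12)
  labels <- c(rep("pathogenic", 6), rep("benign", 6))
  spec <- toolSpec(REG, "M-CAP")
  aucs <- replicate(1000, auc(rocCurve(sc, sample(labels), spec)))
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("the Youden optimum recovers the class-density crossing at large n", {
  set.seed(808)
  n <- 10000
  mu1 <- 0.2; s1 <- 0.05          # pathogenic (lower is damaging)
  mu0 <- 0.5; s0 <- 0.10          # benign
  sc <- c(rnorm(n, mu1, s1), rnorm(n, mu0, s0))
  labels <- c(rep("pathogenic", n), rep("benign", n))
  r <- rocCurve(sc, labels, toolSpec(REG, "SIFT"))
  # closed-form crossing of the two normal densities (equal priors)
  a <- 1 / (2 * s1^2) - 1 / (2 * s0^2)
  b <- mu0 / s0^2 - mu1 / s1^2
  cc <- mu1^2 / (2 * s1^2) - mu0^2 / (2 * s0^2) + log(s0 / s1)
  roots <- Re(polyroot(c(cc, b, a)))
  crossing <- roots[roots > mu1 & roots < mu0]
  expect_length(crossing, 1)
  expect_lt(abs(optimalThreshold(r) - crossing), 0.03)
})

test_that("optimal-vs-recommended direction is orientation aware", {
  spec <- toolSpec(REG, "SIFT")
  # heavy benign mass between 0.004 and 0.05 drags the optimum stricter
  set.seed(9)
  sc <- c(runif(200, 1e-4, 0.004), runif(200, 0.004, 0.05))
  labels <- c(rep("pathogenic", 200), rep("benign", 200))
  r <- rocCurve(sc, labels, spec)
  cmp <- compareCutoffs(r, spec)
  expect_equal(cmp$direction, "optimal_stricter")
  expect_lt(cmp$optimal, spec$cutoff)

  eq <- spec; eq$cutoff <- optimalThreshold(r)
  expect_equal(compareCutoffs(r, eq)$direction, "equal")

  hi <- toolSpec(REG, "M-CAP")
  r2 <- rocCurve(c(0.6, 0.7, 0.8, 0.1, 0.5),
                 c(rep("pathogenic", 3), rep("benign", 2)), hi)
  cmp2 <- compareCutoffs(r2, hi)   # optimum above the recommendation
  expect_gt(cmp2$optimal, hi$cutoff)
  expect_equal(cmp2$direction, "optimal_stricter")
})

test_that("the Spearman matrix is symmetric, bounded, rank-invariant and signed", {
  panels <- randomPanels(80, seed = 4)
  cm <- spearmanMatrix(panels)
  r <- rho(cm)
  expect_equal(r, t(r))
  expect_true(all(abs(r[is.finite(r)]) <= 1 + 1e-12))
  expect_true(all(diag(r) == 1))

  # invariance under a per-tool strictly increasing transform
  tr <- panels@scores
  tr$SIFT <- exp(tr$SIFT)
  tr[["M-CAP"]] <- tr[["M-CAP"]]^3 + 5
  cm2 <- spearmanMatrix(ScorePanelSet(tr, REG, panels@variantIds))
  expect_equal(rho(cm2), r, tolerance = 1e-12)

  # opposite orientations around a shared latent damage variable
  set.seed(12)
  latent <- runif(100)
  sc <- data.frame(SIFT = 1 - latent + rnorm(100, 0, 0.02),   # lower damaging
                   "M-CAP" = latent + rnorm(100, 0, 0.02),    # higher damaging
                   check.names = FALSE)
  cm3 <- spearmanMatrix(ScorePanelSet(sc, REG, sprintf("l%03d", 1:100)))
  expect_lt(rho(cm3)["SIFT", "M-CAP"], -0.9)

  # fewer than 3 complete pairs is undefined
  sc4 <- data.frame(SIFT = c(0.1, 0.2, NA, NA),
                    "M-CAP" = c(NA, NA, 0.3, 0.4), check.names = FALSE)
  cm4 <- spearmanMatrix(ScorePanelSet(sc4, REG, sprintf("u%d", 1:4)))
  expect_true(is.na(rho(cm4)["SIFT", "M-CAP"]))
  expect_equal(nPairs(cm4)["SIFT", "M-CAP"], 0L)
})
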