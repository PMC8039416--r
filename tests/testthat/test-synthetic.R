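test_that("generators are deterministic under a seed and diverge across seeds", {
  a <- generateFixture(seed = 5, manifest = data.frame(
    source = "synthetic", gene = "COL4A3", label_class = "benign",
    n_total = 25, n_target_predicted_pathogenic = 2))
  b <- generateFixture(seed = 5, manifest = data.frame(
    source = "synthetic", gene = "COL4A3", label_class = "benign",
    n_total = 25, n_target_predicted_pathogenic = 2))
  expect_identical(a$variants, b$variants)
  expect_identical(a$panels@scores, b$panels@scores)

  # distinct seeds give distinct panels (collision check)
  sigs <- vapply(1:100, function(s) {
    p <- generateScorePanels(generatorParams(
      seed = s, n_per_stratum = data.frame(source = "synthetic",
                                           gene = "COL4A3",
                                           label_class = "pathogenic",
                                           n = 3)))
    paste(signif(unlist(Filter(is.numeric, p$panels@scores)), 8),
          collapse = ",")
  }, character(1))
  expect_equal(anyDuplicated(sigs), 0)
})

test_that("class-conditional panels separate: consensus sens/spec above 0.95", {
  params <- generatorParams(seed = 1234, n_per_stratum = data.frame(
    source = "synthetic", gene = "COL4A3",
    label_class = c("pathogenic", "benign"), n = 10000))
  g <- generateScorePanels(params)
  calls <- classifyCohort(g$panels)
  pred <- isPredictedPathogenic(calls)
  path <- g$variants$clinical_label == "pathogenic"
  expect_gt(mean(pred[path]), 0.95)        # sensitivity
  expect_gt(mean(!pred[!path]), 0.95)      # specificity
  # all generated frequencies lie in [0, 1]
  af <- unlist(g$variants[afColumns(g$variants)])
  expect_true(all(is.na(af) | (af >= 0 & af <= 1)))
})

test_that("three tools withholding all output forbids any pathogenic call", {
  model <- defaultScoreModel()
  model$missing_rate[model$tool %in% c("SIFT", "LRT", "M-CAP")] <- 1
  params <- generatorParams(seed = 3, n_per_stratum = data.frame(
    source = "synthetic", gene = "COL4A5", label_class = "pathogenic",
    n = 300), score_model = model)
  g <- generateScorePanels(params)
  calls <- classifyCohort(g$panels)
  expect_true(all(nMissing(calls) >= 3))
  expect_false(any(isPredictedPathogenic(calls)))
})

test_that("count-manifest fixtures self-verify against re-classification", {
  set.seed(99)
  for (i in 1:3) {
    man <- data.frame(source = "synthetic",
                      gene = sample(c("COL4A3", "COL4A4", "COL4A5"), 3),
                      label_class = c("pathogenic", "benign", "vus"),
                      n_total = sample(5:40, 3))
    man$n_target_predicted_pathogenic <- vapply(
      man$n_total, function(n) sample(0:n, 1), integer(1))
    fx <- generateFixture(manifest = man, seed = 100 + i)
    calls <- classifyCohort(fx$panels)
    for (r in seq_len(nrow(man))) {
      sel <- fx$variants$gene == man$gene[r] &
        fx$variants$clinical_label == man$label_class[r]
      expect_equal(sum(isPredictedPathogenic(calls)[sel]),
                   man$n_target_predicted_pathogenic[r])
    }
  }
  expect_error(generateFixture(manifest = data.frame(
    source = "synthetic", gene = "COL4A3", label_class = "benign",
    n_total = 3, n_target_predicted_pathogenic = 5)), "infeasible")
})

test_that("the packaged manifests load and are internally consistent", {
  ps <- fixtureManifest("prediction_strata")
  expect_true(all(ps$n_target_predicted_pathogenic <= ps$n_total))
  fp <- fixtureManifest("functional_panel")
  expect_equal(sum(fp$n_total), 17)
  expect_equal(sum(fp$n_total[fp$label_class == "pathogenic"]), 9)
  fc <- fixtureManifest("fsgs_cohort")
  expect_equal(sum(fc$n_total), 70)
  expect_equal(sum(fc$n_rare_missense) + sum(fc$n_rare_stopgain), 31)
})

test_that("RLU generation plants defects exactly and respects the noiseless limit", {
  params <- generatorParams(seed = 8)
  plan <- data.frame(
    mutant_id = c("WT", sprintf("p%d", 1:9)), gene = "COL4A5",
    terminal = "N", label = c("wild_type", rep("pathogenic", 9)),
    plant_defect = c(FALSE, rep(TRUE, 9)), stringsAsFactors = FALSE)
  rlu <- generateRlu(params, plan, seed = 8)
  expect_true(all(rlu$intracellular_rlu >= 0 & rlu$secreted_rlu >= 0))
  dc <- defectCalls(callSecretoryDefect(summarizeReplicates(rlu, "N"), 50))
  expect_equal(sum(dc$defect), 9)

  none <- plan; none$plant_defect <- FALSE
  rlu0 <- generateRlu(params, none, seed = 9)
  dc0 <- defectCalls(callSecretoryDefect(summarizeReplicates(rlu0, "N"), 50))
  expect_equal(sum(dc0$defect), 0)

  # replicate_sd -> 0: calls equal the planted geometry exactly, and the
  # planted drop appears verbatim in the means
  tiny <- generatorParams(seed = 8, rlu_model = list(
    wt_intracellular = 500, wt_secreted = 500, defect_drop = 200,
    replicate_sd = 1e-9, n_replicates = 3))
  rluT <- generateRlu(tiny, plan, seed = 10)
  sT <- summarizeReplicates(rluT, "N")
  m <- sT[sT$mutant_id != "WT", ]
  expect_equal(m$mean_secreted, m$mean_intracellular - 200,
               tolerance = 1e-6)

  expect_error(generateRlu(params, plan[-1, ], seed = 8), "WT")
  badplan <- plan
  bad <- generatorParams(seed = 8, rlu_model = list(
    wt_intracellular = 500, wt_secreted = 500, defect_drop = 60,
    replicate_sd = 10, n_replicates = 3))
  expect_error(generateRlu(bad, badplan, seed = 8), "defect_drop")
})

test_that("generator parameter validation rejects degenerate models", {
  expect_error(generatorParams(score_model = within(defaultScoreModel(),
                                                    missing_rate <- 1.5)),
               "missing_rate")
  m <- defaultScoreModel(); m$damaging_sd[1] <- 0
  expect_error(generatorParams(score_model = m), "sds")
  expect_error(generatorParams(af_model = list(p_absent = 0, lo = 0.1,
                                               hi = 0.01)), "af model")
})
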