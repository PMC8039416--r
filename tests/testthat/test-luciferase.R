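rluRow <- function(mutant, gene, terminal, rep, ic, sec,
                   label = "vus") {
  data.frame(mutant_id = mutant, gene = gene, terminal = terminal,
             replicate = rep, intracellular_rlu = ic, secreted_rlu = sec,
             label = label, stringsAsFactors = FALSE)
}

test_that("replicates summarize to arithmetic means per mutant", {
  tab <- rbind(rluRow("WT", "COL4A3", "N", 1:3, c(490, 500, 510),
                      c(495, 505, 515), "wild_type"),
               rluRow("m1", "COL4A3", "N", 1:3, c(100, 110, 120),
                      c(90, 100, 110)),
               rluRow("m2", "COL4A3", "N", 1, 200, 180))
  s <- summarizeReplicates(validateRluTable(tab), "N")
  expect_equal(s$mean_intracellular[s$mutant_id == "m1"], 110)
  expect_equal(s$n_replicates[s$mutant_id == "m1"], 3)
  expect_equal(s$mean_secreted[s$mutant_id == "m2"], 180)  # single replicate
  # a mutant with no replicates at the requested terminal is dropped loudly
  tab2 <- rbind(tab, rluRow("m3", "COL4A3", "C", 1, 150, 150))
  expect_warning(s2 <- summarizeReplicates(validateRluTable(rbind(
    tab2, rluRow("WT", "COL4A3", "C", 1, 500, 500, "wild_type"))), "N"),
    "m3")
  expect_false("m3" %in% s2$mutant_id)
})

test_that("replicate noise averages out: recovered means within 3 standard errors", {
  set.seed(14)
  for (i in 1:20) {
    mu_ic <- runif(1, 100, 600); mu_sec <- runif(1, 100, 600); sd <- 12
    tab <- rluRow("m", "COL4A5", "N", 1:3, rnorm(3, mu_ic, sd),
                  rnorm(3, mu_sec, sd))
    tab <- rbind(tab, rluRow("WT", "COL4A5", "N", 1:3, 500, 500,
                             "wild_type"))
    s <- summarizeReplicates(tab, "N")
    se <- sd / sqrt(3)
    expect_lt(abs(s$mean_intracellular[s$mutant_id == "m"] - mu_ic), 4 * se)
    expect_lt(abs(s$mean_secreted[s$mutant_id == "m"] - mu_sec), 4 * se)
  }
})

test_that("the band rule calls defects under the Y = X - band line only", {
  s <- summaryFromPattern(c(TRUE, FALSE))        # (200,100) and (200,200)
  calls <- defectCalls(callSecretoryDefect(s, 50))
  expect_equal(calls$defect[calls$mutant_id == "m01"], TRUE)   # 100 < 150
  expect_equal(calls$defect[calls$mutant_id == "m02"], FALSE)  # on Y = X
  expect_false(calls$defect[calls$mutant_id == "WT"])
  # a dataset whose WT violates the band is rejected as miscalibrated
  bad <- s; bad$mean_secreted[bad$mutant_id == "WT"] <- 100
  expect_error(callSecretoryDefect(bad, 50), "calibration error")
  expect_error(callSecretoryDefect(s[s$mutant_id != "WT", ], 50), "WT")
})

test_that("widening the band never creates a defect; scaling is covariant", {
  set.seed(23)
  s <- summaryFromPattern(runif(12) < 0.5)
  s$mean_secreted <- s$mean_secreted + runif(nrow(s), -30, 30)
  s$mean_secreted[s$mutant_id == "WT"] <- s$mean_intracellular[s$mutant_id == "WT"]
  bands <- c(20, 50, 120)
  got <- lapply(bands, function(b) defectCalls(callSecretoryDefect(s, b))$defect)
  expect_true(all(got[[2]] <= got[[1]]))
  expect_true(all(got[[3]] <= got[[2]]))
  for (f in c(0.1, 3, 40)) {
    sf <- s
    sf$mean_intracellular <- sf$mean_intracellular * f
    sf$mean_secreted <- sf$mean_secreted * f
    expect_identical(defectCalls(callSecretoryDefect(sf, 50 * f))$defect,
                     got[[2]])
  }
  # the optional WT-referenced rescaling reproduces the raw-scale calls
  # when the band is scaled the same way
  f <- 100 / s$mean_intracellular[s$mutant_id == "WT"]
  expect_identical(
    defectCalls(callSecretoryDefect(s, 50 * f, rescale_wt = TRUE))$defect,
    got[[2]])
})

test_that("the functional panel shows 9 pathogenic and 1 VUS N-terminal defects", {
  fn <- generateFunctionalFixture(seed = 42)
  dcN <- callSecretoryDefect(summarizeReplicates(fn$rlu, "N"), 50)
  cl <- defectCalls(dcN)
  cl <- cl[cl$mutant_id != "WT", ]
  expect_equal(sum(cl$defect[cl$label == "pathogenic"]), 9)
  expect_equal(sum(cl$defect[cl$label == "vus"]), 1)
  expect_equal(sum(cl$defect[cl$label == "vus" & cl$gene == "COL4A5"]), 1)
})

test_that("terminal comparison flags exactly the Hamming-distance mutants", {
  a <- callSecretoryDefect(summaryFromPattern(c(TRUE, FALSE, TRUE), terminal = "N"), 50)
  b <- callSecretoryDefect(summaryFromPattern(c(FALSE, FALSE, TRUE), terminal = "C"), 50)
  cmp <- suppressMessages(compareTerminals(a, b))
  expect_equal(cmp$discordant[cmp$mutant_id == "m01"], TRUE)
  expect_equal(sum(cmp$discordant), 1)
  set.seed(31)
  for (i in 1:10) {
    pn <- runif(8) < 0.5; pc <- runif(8) < 0.5
    dn <- callSecretoryDefect(summaryFromPattern(pn, terminal = "N"), 50)
    dc <- callSecretoryDefect(summaryFromPattern(pc, terminal = "C"), 50)
    expect_equal(sum(suppressMessages(compareTerminals(dn, dc))$discordant),
                 sum(pn != pc))
  }
  short <- callSecretoryDefect(summaryFromPattern(TRUE), 50)
  expect_error(suppressMessages(compareTerminals(a, short)),
               "mismatched mutant sets")
})

test_that("N- and C-terminal calls disagree for some pathogenic fixture mutants", {
  fn <- generateFunctionalFixture(seed = 42)
  dcN <- callSecretoryDefect(summarizeReplicates(fn$rlu, "N"), 50)
  dcC <- callSecretoryDefect(summarizeReplicates(fn$rlu, "C"), 50)
  cmp <- suppressMessages(compareTerminals(dcN, dcC))
  path_ids <- fn$plan$mutant_id[fn$plan$label == "pathogenic"]
  expect_gt(sum(cmp$discordant[cmp$mutant_id %in% path_ids]), 0)
})

test_that("congruence reproduces the functional panel's printed fractions", {
  fn <- generateFunctionalFixture(seed = 42)
  calls <- classifyCohort(fn$panels)
  dcN <- callSecretoryDefect(summarizeReplicates(fn$rlu, "N"), 50)
  cong <- functionalCongruence(dcN, calls, fn$variants)
  get <- function(g, l, col)
    cong[cong$gene == g & cong$label_class == l, col]
  expect_equal(get("COL4A3", "pathogenic", "congruence"), 1.0)
  expect_equal(get("COL4A5", "pathogenic", "congruence"), 1.0)
  expect_equal(get("COL4A3", "vus", "n_predicted_deleterious"), 3)
  expect_equal(get("COL4A3", "vus", "congruence"), 0.0)
  expect_equal(get("COL4A5", "vus", "n_predicted_deleterious"), 2)
  expect_equal(get("COL4A5", "vus", "congruence"), 0.5)
})

test_that("congruence is undefined, not zero, without predicted-deleterious variants", {
  ids <- c("m1", "m2")
  vt <- variantsFor(ids, label = "vus", source = "FSGS")
  sc <- data.frame(SIFT = c(0.9, 0.9))            # nobody predicted
  calls <- classifyCohort(ScorePanelSet(sc, REG, ids))
  s <- summaryFromPattern(c(TRUE, FALSE))
  s$mutant_id <- c("WT", ids)
  dc <- callSecretoryDefect(s, 50)
  cong <- functionalCongruence(dc, calls, vt)
  expect_true(is.na(cong$congruence))
  expect_equal(cong$n_with_defect, 1)
})
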