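# small deterministic feature-table cohorts for classifier tests
toyCohort <- function(n = 30, seed = 1, sep = 2) {
  set.seed(seed)
  lab <- rep(c("control", "ild"), each = n / 2)
  x <- cbind(V1 = rnorm(n) + (lab == "ild") * sep,
             V2 = rnorm(n) + (lab == "ild") * sep * 0.5,
             V4 = rnorm(n) - (lab == "ild") * sep * 0.5,
             V5 = rnorm(n) - (lab == "ild") * sep * 0.4,
             N1 = rnorm(n), N2 = rnorm(n))
  list(x = x, y = lab)
}

test_that("MEAN uses exactly one predictor; MSSK exactly four", {
  d <- toyCohort()
  mean_fit <- tuneModel(modelSpec("MEAN", seed = 2), d)
  expect_identical(mean_fit$features, "V1")
  expect_length(mean_fit$beta, 1L)
  mssk <- tuneModel(modelSpec("MSSK", seed = 2), d)
  expect_identical(mssk$features, c("V1", "V2", "V4", "V5"))
})

test_that("a separable source tunes to near-perfect AUC", {
  d <- toyCohort(sep = 8)
  for (arch in c("MEAN", "MSSK", "ML")) {
    spec <- modelSpec(arch, nSamples = 30L, seed = 3)
    fit <- tuneModel(spec, d)
    expect_gte(fit$aucTuning, 0.95)
  }
})

test_that("tuning is deterministic under a fixed seed", {
  fs <- simulateFeatureCohort(20, 20, seed = 5)
  a <- tuneModel(modelSpec("ML", nSamples = 50L, seed = 11), fs, domain = "microct")
  b <- tuneModel(modelSpec("ML", nSamples = 50L, seed = 11), fs, domain = "microct")
  expect_identical(a$features, b$features)
  expect_identical(a$aucTuning, b$aucTuning)
  expect_identical(a$beta, b$beta)
})

test_that("standardization statistics come from training folds only", {
  fs <- simulateFeatureCohort(20, 20, seed = 6)
  fit <- tuneModel(modelSpec("ML", nSamples = 20L, seed = 7), fs, domain = "microct")
  xy <- xlung:::asXY(fs, "microct")
  for (fi in c(1L, 5L)) {
    tr <- setdiff(seq_len(nrow(xy$x)), fit$folds[[fi]])
    expect_equal(fit$foldCenters[[fi]], colMeans(xy$x[tr, , drop = FALSE]))
  }
})

test_that("degenerate transfer: target = source reproduces training performance", {
  d <- toyCohort(n = 60, seed = 8, sep = 3)
  fit <- tuneModel(modelSpec("MSSK", seed = 9), d)
  tt <- testTransfer(fit, d, nBoot = 200, seed = 1)
  trainAuc <- directionalAuc(predictScores(fit, d$x), d$y)$auc
  expect_equal(tt$auc, trainAuc)
  expect_lt(abs(tt$auc - fit$aucTuning), 0.1)
  re <- reoptimize(fit, d, seed = 2)
  expect_lt(abs(re$aucReopt - fit$aucTuning), 0.1)
})

test_that("label-permuted target scores at chance within its CI", {
  d <- toyCohort(n = 60, seed = 10, sep = 3)
  fit <- tuneModel(modelSpec("MEAN", seed = 11), d)
  set.seed(123)
  dPerm <- list(x = d$x, y = sample(d$y))
  tt <- testTransfer(fit, dPerm, nBoot = 500, seed = 3)
  expect_gt(0.5, tt$ci[1])
  expect_lt(0.5, tt$ci[2])
})

test_that("re-optimization keeps the frozen signature and absorbs pure shifts", {
  fs <- simulateFeatureCohort(20, 20, seed = 12)
  fit <- tuneModel(modelSpec("ML", nSamples = 30L, seed = 13), fs, domain = "microct")
  xy <- xlung:::asXY(fs, "microct")
  shifted <- list(x = sweep(xy$x, 2, rep(5, ncol(xy$x)), "+"), y = xy$y)
  re <- reoptimize(fit, shifted, seed = 14)
  expect_identical(re$model$features, fit$features)
  # a constant feature shift is absorbed by refit standardization
  reSame <- reoptimize(fit, xy, seed = 14)
  expect_equal(re$aucReopt, reSame$aucReopt, tolerance = 1e-10)
  expect_lt(abs(re$aucReopt - fit$aucTuning), 0.12)
})

test_that("missing feature columns in the target are an error", {
  d <- toyCohort()
  fit <- tuneModel(modelSpec("MSSK", seed = 15), d)
  expect_error(predictScores(fit, d$x[, c("V1", "V2")]), "missing feature")
})

test_that("Youden diagnostics match an exhaustive threshold scan", {
  scores <- c(0.9, 0.8, 0.4, 0.3, 0.2)
  labels <- c("ild", "ild", "ild", "control", "control")
  # brute force over every candidate cutoff
  cand <- sort(unique(scores))
  pos <- labels == "ild"
  J <- vapply(cand, function(cc)
    mean(scores[pos] >= cc) + mean(scores[!pos] < cc) - 1, numeric(1))
  expect_equal(max(J), 1)
  d <- thresholdDiagnostics(scores, labels, nBoot = 100, seed = 1)
  expect_equal(d$cutoff, cand[which.max(J)])
  expect_equal(d$J, 1)
  m <- d$metrics
  expect_equal(m$value[m$metric == "TPR"], 1)
  expect_equal(m$value[m$metric == "TNR"], 1)
  expect_equal(m$value[m$metric == "LRpos"], Inf)
  expect_equal(m$value[m$metric == "LRneg"], 0)
  # anti-informative scores: best J is 0 with TPR + TNR = 1
  flip <- thresholdDiagnostics(c(0.1, 0.2, 0.8, 0.9),
                               c("ild", "ild", "control", "control"),
                               nBoot = 50, seed = 1)
  expect_equal(flip$J, 0, tolerance = 1e-12)
})

test_that("likelihood ratios obey their definitional identity at the cutoff", {
  set.seed(21)
  scores <- c(rnorm(25, 1), rnorm(25))
  labels <- rep(c("ild", "control"), each = 25)
  d <- thresholdDiagnostics(scores, labels, nBoot = 100, seed = 2)
  m <- setNames(d$metrics$value, d$metrics$metric)
  expect_equal(unname(m["LRpos"]), unname(m["TPR"] / (1 - m["TNR"])))
  expect_equal(unname(m["LRneg"]), unname((1 - m["TPR"]) / m["TNR"]))
})

test_that("MSSK coefficient signs follow the construction; negation flips them", {
  # partial coefficients of correlated moments are noisy in any one cohort;
  # the direction pattern is a seed-averaged property
  betas <- vapply(1:6, function(s) {
    fsS <- simulateFeatureCohort(40, 40, seed = s)
    tuneModel(modelSpec("MSSK", seed = s), fsS, domain = "microct")$beta
  }, numeric(4))
  expect_equal(unname(sign(rowMeans(betas))), c(1, 1, -1, -1))
  fs <- simulateFeatureCohort(30, 30, seed = 16)
  fit <- tuneModel(modelSpec("MSSK", seed = 17), fs, domain = "microct")
  xy <- xlung:::asXY(fs, "microct")
  xNeg <- xy$x
  xNeg[, "V4"] <- -xNeg[, "V4"]
  fitNeg <- tuneModel(modelSpec("MSSK", seed = 17), list(x = xNeg, y = xy$y))
  expect_equal(sign(fitNeg$beta["V4"]), -sign(fit$beta["V4"]))
})

test_that("zero-effect features rank below informative ones in selection", {
  d <- toyCohort(n = 80, seed = 18, sep = 2.5)
  fit <- tuneModel(modelSpec("ML", nSamples = 40L, seed = 19), d)
  expect_true(fit$features[1] %in% c("V1", "V2", "V4", "V5"))
})

test_that("bootstrap AUC confidence intervals have near-nominal coverage", {
  # scores ~ N(1,1) vs N(0,1): true AUC = pnorm(1/sqrt(2))
  trueAuc <- pnorm(1 / sqrt(2))
  model <- structure(list(architecture = "MEAN", features = "V1",
                          center = c(V1 = 0), scale = c(V1 = 1),
                          intercept = 0, beta = c(V1 = 1), lambda = 0,
                          positive = "ild"), class = "xlungModel")
  set.seed(31)
  hits <- vapply(1:150, function(i) {
    x <- matrix(c(rnorm(30, 1), rnorm(30)), ncol = 1,
                dimnames = list(NULL, "V1"))
    y <- rep(c("ild", "control"), each = 30)
    tt <- testTransfer(model, list(x = x, y = y), nBoot = 400, seed = i)
    tt$ci[1] <= trueAuc && trueAuc <= tt$ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 0.99)
})
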