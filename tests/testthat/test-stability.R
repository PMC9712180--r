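# build a feature set with explicit observer structure from a value matrix
# generator: vals(subject, observer, repetition) -> numeric vector of
# featureIds values
syntheticStabilitySet <- function(featureIds, nSubj, domains = c("microct", "hrct"),
                                  vals, nObservers = 3, nRepeats = 2) {
  cols <- list()
  info <- list()
  for (dom in domains) for (i in seq_len(nSubj)) {
    combos <- rbind(data.frame(observer = 0L, repetition = 0L),
                    data.frame(observer = seq_len(nObservers), repetition = 1L),
                    data.frame(observer = 1L, repetition = 2:nRepeats))
    for (j in seq_len(nrow(combos))) {
      cols[[length(cols) + 1L]] <- vals(i, combos$observer[j],
                                        combos$repetition[j], dom)
      info[[length(info) + 1L]] <- data.frame(
        subject = paste0(dom, i), domain = dom, label = "control",
        observer = combos$observer[j], repetition = combos$repetition[j])
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- featureIds
  RadiomicsFeatureSet(m, do.call(rbind, info),
                      family = rep("HIST", length(featureIds)))
}

test_that("consistency ICC has its defining invariances", {
  y <- matrix(c(1, 2, 3, 4, 5, 1.1, 2.2, 2.9, 4.2, 4.8), 5, 2)
  expect_equal(iccConsistency(cbind(y[, 1], y[, 1]))$icc, 1)
  # additive rater bias is ignored by the consistency form
  expect_equal(iccConsistency(cbind(y[, 1], y[, 1] + 100))$icc, 1)
  # common affine rescaling of all raters leaves ICC unchanged
  a <- iccConsistency(y)$icc
  b <- iccConsistency(y * 3.7 - 42)$icc
  expect_equal(a, b, tolerance = 1e-12)
  # all ratings identical: perfect agreement
  same <- iccConsistency(matrix(5, 3, 2))
  expect_equal(same$icc, 1)
  # zero between-subject variance with rater structure: undefined
  flat <- iccConsistency(cbind(c(5, 5, 5), c(7, 7, 7)))
  expect_true(flat$undefined)
  expect_true(is.na(flat$icc))
})

test_that("ICC matches a two-way ANOVA computed by lm/aov", {
  oracleIcc <- function(m) {
    d <- data.frame(value = as.vector(m),
                    subject = factor(rep(seq_len(nrow(m)), ncol(m))),
                    rater = factor(rep(seq_len(ncol(m)), each = nrow(m))))
    ms <- summary(stats::aov(value ~ subject + rater, data = d))[[1]][, "Mean Sq"]
    (ms[1] - ms[3]) / (ms[1] + (ncol(m) - 1) * ms[3])
  }
  fixed <- matrix(c(9, 6, 8, 7, 10, 6,
                    2, 1, 4, 1, 5, 2,
                    5, 3, 6, 2, 6, 4), 6, 3)
  expect_equal(iccConsistency(fixed)$icc, oracleIcc(fixed), tolerance = 1e-10)
  for (seed in 1:20) {
    set.seed(seed)
    m <- matrix(rnorm(30), 10, 3) + rnorm(10)
    expect_equal(iccConsistency(m)$icc, oracleIcc(m), tolerance = 1e-10,
                 info = paste("seed", seed))
  }
})

test_that("stability filter: identity under perfect agreement, empty above 1", {
  ids <- paste0("V", 1:6)
  base <- matrix(rnorm(6 * 10), 6, 10)
  perfect <- syntheticStabilitySet(ids, 10, vals = function(i, o, r, dom)
    base[, i] + ifelse(dom == "hrct", 3, 0))
  res <- stabilityFilter(perfect, threshold = 0.75)
  expect_setequal(res$retained, ids)
  none <- stabilityFilter(perfect, threshold = 1.01)
  expect_length(none$retained, 0L)
  # a filter with threshold -Inf is the identity on the feature set
  all <- stabilityFilter(perfect, threshold = -Inf)
  expect_setequal(all$retained, ids)
})

test_that("noisy observers push features below the stability threshold", {
  ids <- paste0("V", 1:4)
  set.seed(99)
  base <- matrix(rnorm(4 * 12), 4, 12)
  noisy <- syntheticStabilitySet(ids, 12, vals = function(i, o, r, dom) {
    v <- base[, i]
    if (o > 0) v[3:4] <- v[3:4] + rnorm(2, sd = 10)   # V3/V4 delineation-sensitive
    v
  })
  res <- stabilityFilter(noisy, threshold = 0.75)
  expect_true(all(c("V1", "V2") %in% res$retained))
  expect_false(any(c("V3", "V4") %in% res$retained))
  fam <- res$familySummary
  expect_equal(fam$unstableFraction[fam$family == "HIST"], 0.5)
})

test_that("boundary jitter destabilizes distance zones at least as much as histogram", {
  out <- file.path(tempdir(), "xlung-stab-img")
  on.exit(unlink(out, recursive = TRUE))
  cfg <- list(nControl = 8L, nIld = 0L, domainTag = "microct",
              gridShape = c(24L, 24L, 24L), spacingMm = c(0.5, 0.5, 0.5))
  cfgM <- do.call(phantomConfig, cfg)
  cfg$domainTag <- "hrct"
  cfgH <- do.call(phantomConfig, cfg)
  obs <- observerPerturbation(nObservers = 2L, nRepeats = 2L,
                              boundaryJitterMm = 1.0, erosionDilationProb = 0.5)
  man <- generateCohort(cfgM, cfgH, obs, out, nStabilityCases = 8L, seed = 31L)
  fs <- extractAll(man, extractionConfig(targetSpacingMm = 0.5))
  res <- stabilityFilter(fs, threshold = 0.75)
  fam <- res$familySummary
  expect_gte(fam$unstableFraction[fam$family == "GLDZM"],
             fam$unstableFraction[fam$family == "HIST"])
})

test_that("aggregation redundancy drops merged variants only when redundant", {
  reg <- featureRegistry()
  nSubj <- 30
  set.seed(8)
  vals <- matrix(rnorm(154 * nSubj), 154, nSubj,
                 dimnames = list(reg$id, NULL))
  info <- data.frame(subject = paste0("s", seq_len(nSubj)), domain = "microct",
                     label = "control", observer = 0L, repetition = 0L)
  avgIds <- reg$id[reg$family == "GLCM_avg"]
  mrgIds <- reg$id[reg$family == "GLCM_merged"]
  # identical aggregations: ICC 1, merged dropped
  vals[mrgIds, ] <- vals[avgIds, ]
  fs <- RadiomicsFeatureSet(vals, info)
  res <- aggregationRedundancy(fs, threshold = 0.8)
  expect_equal(unname(res$icc["GLCM"]), 1)
  expect_setequal(res$dropped, mrgIds)            # GLRLM columns independent
  expect_lt(abs(unname(res$icc["GLRLM"])), 0.35)  # near-zero for random pairs
  # drop rule disabled: all 154 features pass through
  res2 <- aggregationRedundancy(fs, threshold = 0.8, drop = FALSE)
  expect_length(res2$kept, 154L)
})
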