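test_that("registry has the 154-feature structure with pinned anchors", {
  reg <- featureRegistry()
  expect_equal(nrow(reg), 154L)
  counts <- table(reg$family)
  expect_equal(unname(counts[c("HIST", "GLCM_avg", "GLCM_merged", "GLRLM_avg",
                               "GLRLM_merged", "GLSZM", "GLDZM", "NGLDM",
                               "NGTDM")]),
               c(17L, 26L, 26L, 16L, 16L, 16L, 16L, 16L, 5L),
               ignore_attr = TRUE)
  anchors <- reg$name[match(c("V1", "V2", "V4", "V5", "V16", "V108", "V141"),
                            reg$id)]
  expect_equal(anchors, c("mean", "sd", "skewness", "kurtosis", "rms",
                          "grayLevelNonUniformityNorm",
                          "depCountNonUniformity"))
})

test_that("histogram features match direct formulas", {
  mk <- function(vals) {
    n <- length(vals)
    list(vol = CTVolume(array(vals, c(n, 1, 1)), c(1, 1, 1)),
         mask = RoiMask(array(TRUE, c(n, 1, 1)), c(1, 1, 1)))
  }
  const <- mk(rep(-400, 5))
  h <- histogramFeatures(const$vol, const$mask)
  expect_equal(unname(h["mean"]), -400)
  expect_equal(unname(h["sd"]), 0)
  expect_equal(unname(h["rms"]), 400)
  three <- mk(c(-1000, -500, 0))
  h3 <- histogramFeatures(three$vol, three$mask)
  expect_equal(unname(h3["mean"]), -500)
  expect_equal(unname(h3["sd"]), 500)              # sample sd, n - 1
  expect_equal(unname(h3["energy"]), 1000^2 + 500^2)
  sym <- mk(c(-10, -5, 0, 5, 10))
  expect_equal(unname(histogramFeatures(sym$vol, sym$mask)["skewness"]), 0)
  expect_error(histogramFeatures(mk(5)$vol, mk(5)$mask), "2 voxels")
})

test_that("GLCM/GLSZM features match hand-computed fixture values", {
  # stripe 1,2,1,2: merged GLCM has only cells (1,2) and (2,1), p = 1/2 each
  stripe <- mkRoi(array(c(1, 2, 1, 2), c(4, 1, 1)), nBins = 2)
  f <- xlung:::glcmFeatures(buildGlcm(stripe), "merged")
  expect_equal(unname(f["contrast"]), 1)           # sum p (i-j)^2 = 1
  expect_equal(unname(f["jointEntropy"]), 1)       # two cells at 1/2
  expect_equal(unname(f["dissimilarity"]), 1)
  expect_equal(unname(f["jointMax"]), 0.5)
  # constant ROI: single-cell limits, never NaN
  const <- mkRoi(array(1L, c(2, 2, 2)), nBins = 1)
  fc <- xlung:::glcmFeatures(buildGlcm(const), "merged")
  expect_equal(unname(fc["jointEntropy"]), 0)
  expect_equal(unname(fc["jointMax"]), 1)
  expect_equal(unname(fc["angularSecondMoment"]), 1)
  expect_false(any(is.na(fc)))
  fz <- xlung:::glszmFeatures(buildGlszm(const))
  expect_equal(unname(fz["grayLevelNonUniformityNorm"]), 1)
  # checkerboard 3x3x1: zones (level 1, size 5) and (level 2, size 4)
  checker <- mkRoi(array(c(1, 2, 1, 2, 1, 2, 1, 2, 1), c(3, 3, 1)), nBins = 2)
  fk <- xlung:::glszmFeatures(buildGlszm(checker))
  expect_equal(unname(fk["smallZoneSizeEmphasis"]), (1 / 25 + 1 / 16) / 2)
  expect_equal(unname(fk["grayLevelNonUniformityNorm"]), 0.5)
  expect_equal(unname(fk["zoneSizePercentage"]), 2 / 9)
  expect_equal(unname(fk["zoneSizeEntropy"]), 1)
})

test_that("whole-subject extraction yields 154 deterministic finite features", {
  cfg <- phantomConfig(domainTag = "microct", gridShape = c(24L, 24L, 24L),
                       spacingMm = c(0.3, 0.3, 0.3))
  ph <- generatePhantom(cfg, "ild", seed = 4L)
  exCfg <- extractionConfig(targetSpacingMm = 0.3)
  f1 <- computeFeatures(ph$volume, ph$mask, exCfg)
  f2 <- computeFeatures(ph$volume, ph$mask, exCfg)
  expect_identical(f1, f2)
  expect_length(f1, 154L)
  expect_identical(names(f1), featureRegistry()$id)
  expect_true(all(is.finite(f1)))
})

test_that("90-degree rotation leaves merged and direction-free features unchanged", {
  cfg <- phantomConfig(domainTag = "microct", gridShape = c(20L, 20L, 20L),
                       spacingMm = c(1, 1, 1))
  ph <- generatePhantom(cfg, "ild", seed = 6L)
  rot <- function(a) {
    b <- aperm(a, c(2, 1, 3))
    b[rev(seq_len(dim(b)[1])), , , drop = FALSE]
  }
  cfgEx <- extractionConfig(targetSpacingMm = NA)
  f <- computeFeatures(ph$volume, ph$mask, cfgEx)
  fr <- computeFeatures(CTVolume(rot(intensities(ph$volume)), c(1, 1, 1)),
                        RoiMask(rot(roiArray(ph$mask)), c(1, 1, 1)), cfgEx)
  reg <- featureRegistry()
  inv <- reg$id[reg$family %in% c("HIST", "GLCM_merged", "GLRLM_merged",
                                  "GLSZM", "GLDZM", "NGLDM", "NGTDM")]
  expect_equal(f[inv], fr[inv], tolerance = 1e-10)
})

test_that("cohort extraction is shaped and guarded as documented", {
  out <- file.path(tempdir(), "xlung-extract-test")
  on.exit(unlink(out, recursive = TRUE))
  cfgM <- phantomConfig(nControl = 2L, nIld = 2L, domainTag = "microct",
                        gridShape = c(16L, 16L, 16L), spacingMm = c(0.3, 0.3, 0.3))
  cfgH <- phantomConfig(nControl = 2L, nIld = 2L, domainTag = "hrct",
                        gridShape = c(16L, 16L, 16L), spacingMm = c(1, 1, 1))
  obs <- observerPerturbation(nObservers = 2L, nRepeats = 2L,
                              boundaryJitterMm = 0.3, erosionDilationProb = 0.2)
  man <- generateCohort(cfgM, cfgH, obs, out, nStabilityCases = 2L, seed = 5L)
  exCfg <- extractionConfig(targetSpacingMm = c(microct = 0.3, hrct = 1.0))
  fs <- extractAll(man, exCfg)
  expect_s4_class(fs, "RadiomicsFeatureSet")
  expect_equal(nrow(fs), 154L)
  expect_equal(ncol(fs), nrow(man))
  fs2 <- extractAll(man, exCfg)
  expect_identical(featureValues(fs), featureValues(fs2))
  # geometry mismatch aborts naming the subject
  bad <- man[man$observer == 0, ][1:2, ]
  bad$mask_path[1] <- bad$mask_path[2]
  badDir <- file.path(out, "bad")
  dir.create(badDir)
  mism <- RoiMask(array(TRUE, c(8L, 8L, 8L)), c(0.3, 0.3, 0.3))
  writeMask(mism, file.path(badDir, "mism.nii.gz"))
  bad$mask_path[1] <- file.path(badDir, "mism.nii.gz")
  expect_error(extractAll(bad, exCfg), bad$subject_id[1])
})
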