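stripeRoi <- function() mkRoi(array(c(1, 2, 1, 2), c(4, 1, 1)), nBins = 2)
checkerRoi <- function() mkRoi(array(c(1, 2, 1, 2, 1, 2, 1, 2, 1), c(3, 3, 1)),
                               nBins = 2)

test_that("GLCM matches hand enumeration on the stripe and is symmetric", {
  g <- buildGlcm(stripeRoi())
  dirs <- directions13()
  dx <- which(dirs[, 1] == 1 & dirs[, 2] == 0 & dirs[, 3] == 0)
  m <- g$counts[, , dx]
  expect_equal(m, matrix(c(0, 3, 3, 0), 2, 2))   # (1,2) and (2,1) three times
  merged <- apply(g$counts, c(1, 2), sum)
  expect_equal(merged, t(merged))
  # merged equals the elementwise sum of the 13 directional matrices by
  # construction; verify against a fresh accumulation
  expect_equal(merged, Reduce(`+`, lapply(1:13, function(d) g$counts[, , d])))
})

test_that("constant ROI gives a single co-occurrence cell", {
  g <- buildGlcm(mkRoi(array(1L, c(2, 2, 2)), nBins = 1))
  merged <- apply(g$counts, c(1, 2), sum)
  expect_equal(dim(merged), c(1L, 1L))
  expect_gt(merged[1, 1], 0)
})

test_that("GLRLM runs match hand enumeration and conserve voxels", {
  r <- buildGlrlm(mkRoi(array(1L, c(1, 1, 4)), nBins = 1))
  dirs <- directions13()
  dz <- which(dirs[, 1] == 0 & dirs[, 2] == 0 & dirs[, 3] == 1)
  expect_equal(r$counts[1, , dz], c(0, 0, 0, 1))  # one run of length 4
  r2 <- buildGlrlm(mkRoi(array(c(1, 1, 2), c(3, 1, 1)), nBins = 2))
  dx <- which(dirs[, 1] == 1 & dirs[, 2] == 0 & dirs[, 3] == 0)
  m <- r2$counts[, , dx]
  expect_equal(m[1, 2], 1)                        # run (level 1, length 2)
  expect_equal(m[2, 1], 1)                        # run (level 2, length 1)
  # conservation per direction: sum(count x length) = ROI voxels
  lens <- seq_len(dim(r2$counts)[2])
  for (d in 1:13)
    expect_equal(sum(r2$counts[, , d] %*% lens), r2$nRoiVoxels)
})

test_that("zones: checkerboard connects diagonally, GLSZM/GLDZM totals agree", {
  z <- buildGlszm(checkerRoi())
  expect_equal(sum(z$counts), 2)                  # 2 zones under 26-connectivity
  expect_equal(z$counts[1, 5], 1)                 # level 1: one zone of 5
  expect_equal(z$counts[2, 4], 1)                 # level 2: one zone of 4
  dz <- buildGldzm(checkerRoi())
  expect_equal(sum(dz$counts), sum(z$counts))
  one <- buildGlszm(mkRoi(array(2L, c(3, 3, 3)), nBins = 2))
  expect_equal(one$counts[2, 27], 1)              # single zone of size 27
})

test_that("GLDZM border distances use the Chebyshev metric", {
  lv <- array(1L, c(5, 5, 5))
  lv[3, 3, 3] <- 2L                               # isolated interior zone
  dz <- buildGldzm(mkRoi(lv, nBins = 2))
  # centre of a 5^3 cube is 3 Chebyshev steps from the nearest outside voxel
  expect_equal(which(dz$counts[2, ] > 0), 3L)
  # the surrounding zone touches the border: distance 1
  expect_equal(which(dz$counts[1, ] > 0), 1L)
})

test_that("NGLDM dependence counts and NGTDM differences match hand values", {
  nd <- buildNgldm(mkRoi(array(1L, c(3, 3, 3)), nBins = 1))
  expect_equal(nd$counts[1, 27], 1)               # centre voxel: dependence 26
  expect_equal(sum(nd$counts), 27)                # conservation
  nt <- buildNgtdm(mkRoi(array(c(1, 2, 1), c(1, 1, 3)), nBins = 2))
  expect_equal(nt$s[2], 1)                        # middle voxel: |2 - mean(1,1)|
  expect_equal(nt$s[1], 2)                        # end voxels: |1 - 2| each
  expect_equal(nt$n, c(2, 1))
})

test_that("all six builders match brute-force enumeration on random ROIs", {
  dirs <- directions13()
  for (seed in 1:40) {
    roi <- randomRoi(seed)
    lv <- grayLevels(roi)
    ng <- nBins(roi)
    g <- buildGlcm(roi)
    r <- buildGlrlm(roi)
    for (d in 1:13) {
      expect_equal(g$counts[, , d], oracleGlcm(lv, dirs[d, ], ng),
                   info = paste("glcm seed", seed, "dir", d))
      oR <- oracleGlrlm(lv, dirs[d, ], ng)
      expect_equal(r$counts[, , d], oR[, seq_len(dim(r$counts)[2])],
                   info = paste("glrlm seed", seed, "dir", d))
    }
    oz <- oracleZones(lv)
    sz <- buildGlszm(roi)
    dzm <- buildGldzm(roi)
    ozS <- matrix(0, ng, max(oz$size))
    ozD <- matrix(0, ng, max(oz$distance))
    for (k in seq_len(nrow(oz))) {
      ozS[oz$level[k], oz$size[k]] <- ozS[oz$level[k], oz$size[k]] + 1
      ozD[oz$level[k], oz$distance[k]] <- ozD[oz$level[k], oz$distance[k]] + 1
    }
    expect_equal(sz$counts, ozS, info = paste("glszm seed", seed))
    expect_equal(dzm$counts, ozD, info = paste("gldzm seed", seed))
    expect_equal(buildNgldm(roi)$counts, oracleNgldm(lv, ng),
                 info = paste("ngldm seed", seed))
    on <- oracleNgtdm(lv, ng)
    nt <- buildNgtdm(roi)
    expect_equal(nt$n, on$n, info = paste("ngtdm-n seed", seed))
    expect_equal(nt$s, on$s, tolerance = 1e-12, info = paste("ngtdm-s seed", seed))
  }
})

test_that("axis permutation leaves merged and direction-free features unchanged", {
  roi <- randomRoi(77, dims = c(5, 4, 3))
  lvP <- aperm(grayLevels(roi), c(2, 3, 1))
  roiP <- mkRoi(lvP, nBins = nBins(roi))
  expect_equal(xlung:::glcmFeatures(buildGlcm(roi), "merged"),
               xlung:::glcmFeatures(buildGlcm(roiP), "merged"))
  expect_equal(xlung:::glrlmFeatures(buildGlrlm(roi), "merged"),
               xlung:::glrlmFeatures(buildGlrlm(roiP), "merged"))
  expect_equal(xlung:::glszmFeatures(buildGlszm(roi)),
               xlung:::glszmFeatures(buildGlszm(roiP)))
  expect_equal(xlung:::ngtdmFeatures(buildNgtdm(roi)),
               xlung:::ngtdmFeatures(buildNgtdm(roiP)))
})

test_that("degenerate ROIs raise the documented errors", {
  expect_error(buildGlcm(mkRoi(array(c(1L, rep(0L, 7)), c(2, 2, 2)))), "2 voxels")
  empty <- new("DiscretizedRoi", levels = array(0L, c(2, 2, 2)), nBins = 1L,
               binWidth = 50, rangeHU = c(-1000, -950), spacing = c(1, 1, 1))
  expect_error(buildGlszm(empty), "empty")
  expect_error(buildNgtdm(empty), "empty")
})
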