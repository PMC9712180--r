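## Texture feature formulas. Features are computed from probability-
## normalized matrices; the count-based non-uniformities use raw counts.
## Degenerate inputs (a single occupied gray level / column) take their
## defined limits — entropies 0, uniformity-type maxima 1 — never NaN.

log2s <- function(p) ifelse(p > 0, log2(p), 0)   # safe p*log2(p) support

## ---------------------------------------------------------------------------
## GLCM
## ---------------------------------------------------------------------------

# 26 features from one symmetric co-occurrence count matrix
glcmFeatureVector <- function(counts) {
  tot <- sum(counts)
  if (tot <= 0) stop("empty co-occurrence matrix")
  P <- counts / tot
  ng <- nrow(P)
  i <- seq_len(ng)
  pi <- rowSums(P)                       # == colSums(P) by symmetry
  mu <- sum(i * pi)
  sig2 <- sum((i - mu)^2 * pi)
  I <- matrix(i, ng, ng)
  J <- t(I)
  D <- abs(I - J)
  S <- I + J
  # difference and sum distributions
  pd <- vapply(0:(ng - 1), function(k) sum(P[D == k]), numeric(1))
  ps <- vapply(2:(2 * ng), function(k) sum(P[S == k]), numeric(1))
  kd <- 0:(ng - 1)
  ks <- 2:(2 * ng)
  diffAvg <- sum(kd * pd)
  sumAvg <- sum(ks * ps)
  hx <- -sum(pi * log2s(pi))
  hxy <- -sum(P * log2s(P))
  PiPj <- outer(pi, pi)
  hxy1 <- -sum(P * log2s(PiPj))
  hxy2 <- -sum(PiPj * log2s(PiPj))
  ic1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  ic2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  corr <- if (sig2 > 0) (sum(I * J * P) - mu^2) / sig2 else 1
  # maximal correlation coefficient on the occupied-level submatrix
  occ <- which(pi > 0)
  mcc <- if (length(occ) <= 1L) 1 else {
    Ps <- P[occ, occ, drop = FALSE]
    ps_i <- pi[occ]
    Q <- matrix(0, length(occ), length(occ))
    for (a in seq_along(occ)) for (b in seq_along(occ))
      Q[a, b] <- sum(Ps[a, ] * Ps[b, ] / (ps_i[a] * ps_i))
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(min(1, max(0, if (length(ev) >= 2) ev[2] else 0)))
  }
  vals <- c(
    jointMax = max(P),
    jointAverage = mu,
    jointVariance = sig2,
    jointEntropy = hxy,
    diffAverage = diffAvg,
    diffVariance = sum((kd - diffAvg)^2 * pd),
    diffEntropy = -sum(pd * log2s(pd)),
    sumAverage = sumAvg,
    sumVariance = sum((ks - sumAvg)^2 * ps),
    sumEntropy = -sum(ps * log2s(ps)),
    angularSecondMoment = sum(P^2),
    contrast = sum(D^2 * P),
    dissimilarity = sum(D * P),
    inverseDifference = sum(P / (1 + D)),
    inverseDifferenceNorm = sum(P / (1 + D / ng)),
    inverseDifferenceMoment = sum(P / (1 + D^2)),
    inverseDifferenceMomentNorm = sum(P / (1 + D^2 / ng^2)),
    inverseVariance = sum(P[D > 0] / D[D > 0]^2),
    correlation = corr,
    autocorrelation = sum(I * J * P),
    clusterTendency = sum((S - 2 * mu)^2 * P),
    clusterShade = sum((S - 2 * mu)^3 * P),
    clusterProminence = sum((S - 2 * mu)^4 * P),
    infoCorr1 = ic1,
    infoCorr2 = ic2,
    maxCorrCoeff = mcc)
  stopifnot(identical(names(vals), glcmFeatureNames()))
  vals
}

# averaged: features per direction, then mean; merged: sum of the 13
# directional matrices, then features
glcmFeatures <- function(glcm, aggregation = c("averaged", "merged")) {
  aggregation <- match.arg(aggregation)
  ct <- glcm$counts
  if (aggregation == "merged") return(glcmFeatureVector(apply(ct, c(1, 2), sum)))
  per <- vapply(seq_len(dim(ct)[3]), function(d) {
    m <- ct[, , d]
    if (sum(m) > 0) glcmFeatureVector(m) else rep(NA_real_, 26)
  }, numeric(26))
  rowMeans(per, na.rm = TRUE)
}

## ---------------------------------------------------------------------------
## run/zone/distance/dependence families (shared 16-feature scheme)
## ---------------------------------------------------------------------------

# counts: nLevels x L matrix; columns carry the attribute (run length, zone
# size, zone distance, dependence count + 1); nv = ROI voxel count
rzFeatureVector <- function(counts, nv, kind) {
  ns <- sum(counts)
  if (ns <= 0) stop("empty matrix")
  ng <- nrow(counts)
  L <- ncol(counts)
  i <- seq_len(ng)
  j <- seq_len(L)
  ri <- rowSums(counts)
  cj <- colSums(counts)
  P <- counts / ns
  mui <- sum(i * ri / ns)
  muj <- sum(j * cj / ns)
  vals <- c(
    sum(t(counts) / j^2) / ns,                       # small emphasis
    sum(t(counts) * j^2) / ns,                       # large emphasis
    sum(counts / i^2) / ns,                          # low gray level
    sum(counts * i^2) / ns,                          # high gray level
    ns / nv,                                         # percentage
    sum(ri^2) / ns,                                  # GLNU
    sum(ri^2) / ns^2,                                # GLNU normalized
    sum(cj^2) / ns,                                  # attribute NU
    sum(cj^2) / ns^2,                                # attribute NU normalized
    sum(outer(1 / i^2, 1 / j^2) * counts) / ns,      # small + low GL
    sum(outer(i^2, 1 / j^2) * counts) / ns,          # small + high GL
    sum(outer(1 / i^2, j^2) * counts) / ns,          # large + low GL
    sum(outer(i^2, j^2) * counts) / ns,              # large + high GL
    sum((i - mui)^2 * ri / ns),                      # gray level variance
    sum((j - muj)^2 * cj / ns),                      # attribute variance
    -sum(P * log2s(P)))                              # entropy
  names(vals) <- rzFeatureNames(kind)
  vals
}

glrlmFeatures <- function(glrlm, aggregation = c("averaged", "merged")) {
  aggregation <- match.arg(aggregation)
  ct <- glrlm$counts
  nv <- glrlm$nRoiVoxels
  if (aggregation == "merged")
    return(rzFeatureVector(apply(ct, c(1, 2), sum), nv * dim(ct)[3], "run"))
  per <- vapply(seq_len(dim(ct)[3]), function(d) {
    m <- ct[, , d]
    if (sum(m) > 0) rzFeatureVector(m, nv, "run") else rep(NA_real_, 16)
  }, numeric(16))
  out <- rowMeans(per, na.rm = TRUE)
  names(out) <- rzFeatureNames("run")
  out
}

glszmFeatures <- function(glszm) rzFeatureVector(glszm$counts, glszm$nRoiVoxels, "zoneSize")
gldzmFeatures <- function(gldzm) rzFeatureVector(gldzm$counts, gldzm$nRoiVoxels, "zoneDist")

# NGLDM: drop every-voxel-counted "energy" analogue is excluded by the
# 16-name scheme; dependence weights use k + 1 (matrix column index), so
# low-dependence emphasis is finite at k = 0
ngldmFeatures <- function(ngldm) {
  ct <- ngldm$counts
  keep <- seq_len(ncol(ct))   # columns are k = 0..26 -> weights 1..27
  rzFeatureVector(ct[, keep, drop = FALSE], ngldm$nRoiVoxels, "depCount")
}

## ---------------------------------------------------------------------------
## NGTDM
## ---------------------------------------------------------------------------

ngtdmFeatures <- function(ngtdm) {
  n <- ngtdm$n
  s <- ngtdm$s
  N <- sum(n)
  if (N <= 0) stop("empty NGTDM")
  p <- n / N
  occ <- which(p > 0)
  ngp <- length(occ)
  i <- seq_along(p)
  coarseDen <- sum(p * s)
  coarseness <- if (coarseDen > 0) 1 / coarseDen else 1e6
  contrast <- if (ngp > 1) {
    (sum(outer(p[occ], p[occ]) * outer(i[occ], i[occ], "-")^2) /
       (ngp * (ngp - 1))) * (sum(s) / N)
  } else 0
  busyDen <- sum(abs(outer(i[occ] * p[occ], i[occ] * p[occ], "-")))
  busyness <- if (busyDen > 0) coarseDen / busyDen else 0
  # complexity / strength accumulate over ordered pairs of occupied levels
  comp <- 0
  stren <- 0
  for (a in occ) for (b in occ) {
    comp <- comp + abs(a - b) * (p[a] * s[a] + p[b] * s[b]) / (p[a] + p[b])
    stren <- stren + (p[a] + p[b]) * (a - b)^2
  }
  complexity <- comp / N
  strength <- if (sum(s) > 0) stren / sum(s) else 0
  vals <- c(coarseness = coarseness, contrast = contrast, busyness = busyness,
            complexity = complexity, strength = strength)
  stopifnot(identical(names(vals), ngtdmFeatureNames()))
  vals
}

## ---------------------------------------------------------------------------
## full texture vector (137 features)
## ---------------------------------------------------------------------------

#' Texture features from built matrices
#'
#' Computes the 137 texture features: 26 GLCM per aggregation (averaged and
#' merged), 16 GLRLM per aggregation, 16 GLSZM, 16 GLDZM, 16 NGLDM and
#' 5 NGTDM, named `V18..V154` in registry order.
#'
#' @param mats Output of [textureMatrices()].
#' @return Named numeric vector of length 137.
#' @export
textureFeatures <- function(mats) {
  c(glcmFeatures(mats$glcm, "averaged"),
    glcmFeatures(mats$glcm, "merged"),
    glrlmFeatures(mats$glrlm, "averaged"),
    glrlmFeatures(mats$glrlm, "merged"),
    glszmFeatures(mats$glszm),
    gldzmFeatures(mats$gldzm),
    ngldmFeatures(mats$ngldm),
    ngtdmFeatures(mats$ngtdm))
}
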