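# Brute-force enumeration oracles, written independently of the package's
# compiled builders: plain-R loops over voxels, pairs and components.

# all 26 neighbour offsets, and the 13 unique directions (first nonzero
# component positive), enumerated here rather than taken from the package
oracleOffsets26 <- local({
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
})
oracleDirs13 <- local({
  keep <- apply(oracleOffsets26, 1, function(v) {
    nz <- v[v != 0]
    nz[1] > 0
  })
  oracleOffsets26[keep, , drop = FALSE]
})

inGrid <- function(p, d) all(p >= 1) && all(p <= d)

# symmetric co-occurrence counts for one direction
oracleGlcm <- function(lv, dir, ng = max(lv), dist = 1L) {
  d <- dim(lv)
  counts <- matrix(0, ng, ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lv[x, y, z]
    if (a == 0) next
    p <- c(x, y, z) + dir * dist
    if (!inGrid(p, d)) next
    b <- lv[p[1], p[2], p[3]]
    if (b == 0) next
    counts[a, b] <- counts[a, b] + 1
    counts[b, a] <- counts[b, a] + 1
  }
  counts
}

# run-length counts for one direction
oracleGlrlm <- function(lv, dir, ng = max(lv), maxlen = max(dim(lv))) {
  d <- dim(lv)
  counts <- matrix(0, ng, maxlen)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lv[x, y, z]
    if (a == 0) next
    prev <- c(x, y, z) - dir
    if (inGrid(prev, d) && lv[prev[1], prev[2], prev[3]] == a) next
    len <- 1
    p <- c(x, y, z) + dir
    while (inGrid(p, d) && lv[p[1], p[2], p[3]] == a) {
      len <- len + 1
      p <- p + dir
    }
    counts[a, len] <- counts[a, len] + 1
  }
  counts
}

# Chebyshev distance of in-mask voxels to nearest outside voxel, by direct
# minimisation (out-of-grid positions count as outside)
oracleChebDist <- function(mask) {
  d <- dim(mask)
  out <- array(0L, d)
  outs <- which(!mask, arr.ind = TRUE)
  for (i in which(mask)) {
    p <- arrayInd(i, d)
    borderD <- min(p, d - p + 1)          # nearest out-of-grid position
    inD <- if (nrow(outs)) min(apply(abs(sweep(outs, 2, as.integer(p))), 1, max))
           else Inf
    out[i] <- min(borderD, inD)
  }
  out
}

# 26-connected equal-level zones: per-zone level, size, min border distance
oracleZones <- function(lv) {
  d <- dim(lv)
  dmap <- oracleChebDist(lv > 0)
  seen <- array(FALSE, d)
  zones <- list()
  for (i in seq_along(lv)) {
    if (lv[i] == 0 || seen[i]) next
    lev <- lv[i]
    queue <- list(arrayInd(i, d))
    seen[i] <- TRUE
    vox <- integer(0)
    while (length(queue)) {
      p <- queue[[1]]
      queue <- queue[-1]
      vox <- c(vox, (p[3] - 1) * d[1] * d[2] + (p[2] - 1) * d[1] + p[1])
      for (k in seq_len(nrow(oracleOffsets26))) {
        q <- as.integer(p) + oracleOffsets26[k, ]
        if (!inGrid(q, d)) next
        if (!seen[q[1], q[2], q[3]] && lv[q[1], q[2], q[3]] == lev) {
          seen[q[1], q[2], q[3]] <- TRUE
          queue[[length(queue) + 1]] <- q
        }
      }
    }
    zones[[length(zones) + 1]] <- data.frame(
      level = lev, size = length(vox), distance = min(dmap[vox]))
  }
  do.call(rbind, zones)
}

# dependence counts (|level difference| <= alpha among in-ROI 26-neighbours)
oracleNgldm <- function(lv, ng = max(lv), alpha = 0L) {
  d <- dim(lv)
  counts <- matrix(0, ng, 27)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lv[x, y, z]
    if (a == 0) next
    k <- 0
    for (o in seq_len(nrow(oracleOffsets26))) {
      p <- c(x, y, z) + oracleOffsets26[o, ]
      if (!inGrid(p, d)) next
      b <- lv[p[1], p[2], p[3]]
      if (b != 0 && abs(b - a) <= alpha) k <- k + 1
    }
    counts[a, k + 1] <- counts[a, k + 1] + 1
  }
  counts
}

oracleNgtdm <- function(lv, ng = max(lv)) {
  d <- dim(lv)
  n <- numeric(ng)
  s <- numeric(ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lv[x, y, z]
    if (a == 0) next
    nb <- c()
    for (o in seq_len(nrow(oracleOffsets26))) {
      p <- c(x, y, z) + oracleOffsets26[o, ]
      if (!inGrid(p, d)) next
      b <- lv[p[1], p[2], p[3]]
      if (b != 0) nb <- c(nb, b)
    }
    if (!length(nb)) next
    n[a] <- n[a] + 1
    s[a] <- s[a] + abs(a - mean(nb))
  }
  list(n = n, s = s)
}

# exhaustive-pair directional AUC
oracleAuc <- function(values, labels, positive = "ild") {
  pos <- values[labels == positive]
  neg <- values[labels != positive]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# wrap an integer level array as a DiscretizedRoi
mkRoi <- function(lv, nBins = max(max(lv), 1L), binWidth = 50) {
  lv <- array(as.integer(lv), dim(lv))
  new("DiscretizedRoi", levels = lv, nBins = as.integer(nBins),
      binWidth = binWidth, rangeHU = c(-1000, -1000 + nBins * binWidth),
      spacing = c(1, 1, 1))
}

# random small ROI with background holes
randomRoi <- function(seed, dims = c(4, 4, 4), ng = 3, pBackground = 0.25) {
  set.seed(seed)
  lv <- array(sample(0:ng, prod(dims), replace = TRUE,
                     prob = c(pBackground, rep((1 - pBackground) / ng, ng))),
              dims)
  if (sum(lv > 0) < 2) lv[c(1, 2)] <- 1L
  mkRoi(lv, nBins = ng)
}

# small quick extraction config for unit-spacing synthetic volumes
unitConfig <- function() extractionConfig(targetSpacingMm = NA,
                                          huRange = c(-1000, 200),
                                          binWidthHu = 50)
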