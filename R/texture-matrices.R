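## Gray-level matrix construction. All builders use the 26-connectivity
## (Chebyshev distance 1) neighbourhood; GLCM/GLRLM use the 13 unique 3D
## direction vectors and support two directional aggregations:
##   averaged — features computed per direction, then averaged;
##   merged   — directional matrices summed, then featurized.

#' Unique 3D directions at Chebyshev distance 1
#'
#' @return A 13 x 3 integer matrix of direction vectors (one per axis pair,
#'   up to sign).
#' @export
directions13 <- function() .cppDirections13()

#' Gray level co-occurrence matrices
#'
#' Symmetric co-occurrence counts for all 13 directions at the given voxel
#' distance; pairs with either voxel outside the ROI are skipped.
#'
#' @param roi A [DiscretizedRoi-class] with at least 2 voxels.
#' @param distance Chebyshev voxel distance (>= 1).
#' @return Object of class `glcmStack`: list with `counts`
#'   (nLevels x nLevels x 13), `nLevels`, `nRoiVoxels`.
#' @export
buildGlcm <- function(roi, distance = 1L) {
  stopifnot(is(roi, "DiscretizedRoi"), distance >= 1)
  nv <- sum(grayLevels(roi) > 0L)
  if (nv < 2L) stop("ROI must contain at least 2 voxels")
  counts <- .cppGlcmStack(grayLevels(roi), nBins(roi), as.integer(distance))
  structure(list(counts = counts, nLevels = nBins(roi), nRoiVoxels = nv),
            class = "glcmStack")
}

#' Gray level run length matrices
#'
#' Maximal runs of equal gray level along each of the 13 directions; voxels
#' outside the ROI break runs. Per direction, the counts satisfy
#' `sum(counts * runLength) == nRoiVoxels`.
#'
#' @param roi A nonempty [DiscretizedRoi-class].
#' @return Object of class `glrlmStack`: `counts`
#'   (nLevels x maxRunLength x 13), `nLevels`, `nRoiVoxels`.
#' @export
buildGlrlm <- function(roi) {
  stopifnot(is(roi, "DiscretizedRoi"))
  nv <- sum(grayLevels(roi) > 0L)
  if (nv < 1L) stop("empty ROI")
  counts <- .cppGlrlmStack(grayLevels(roi), nBins(roi))
  structure(list(counts = counts, nLevels = nBins(roi), nRoiVoxels = nv),
            class = "glrlmStack")
}

# zones = 26-connected components of equal gray level, with the minimum
# Chebyshev distance of any zone voxel to the nearest non-ROI voxel
# (out-of-grid counts as non-ROI; a border voxel has distance 1)
zoneTable <- function(roi) {
  stopifnot(is(roi, "DiscretizedRoi"))
  if (!any(grayLevels(roi) > 0L)) stop("empty ROI")
  .cppZones(grayLevels(roi))
}

#' Gray level size zone / distance zone matrices
#'
#' Zones are 26-connected components of equal gray level. The GLSZM keys
#' zones by size; the GLDZM keys the same zones by their minimum Chebyshev
#' distance to the nearest non-ROI voxel (minimum 1), so both matrices
#' always hold the same total zone count.
#'
#' @param roi A nonempty [DiscretizedRoi-class].
#' @return Object of class `glszm` / `gldzm`: `counts`
#'   (nLevels x maxSize or maxDistance), `nLevels`, `nRoiVoxels`.
#' @export
buildGlszm <- function(roi) {
  z <- zoneTable(roi)
  ng <- nBins(roi)
  counts <- matrix(0, ng, max(z$size))
  for (k in seq_len(nrow(z))) counts[z$level[k], z$size[k]] <-
      counts[z$level[k], z$size[k]] + 1
  structure(list(counts = counts, nLevels = ng,
                 nRoiVoxels = sum(grayLevels(roi) > 0L)), class = "glszm")
}

#' @rdname buildGlszm
#' @export
buildGldzm <- function(roi) {
  z <- zoneTable(roi)
  ng <- nBins(roi)
  counts <- matrix(0, ng, max(z$distance))
  for (k in seq_len(nrow(z))) counts[z$level[k], z$distance[k]] <-
      counts[z$level[k], z$distance[k]] + 1
  structure(list(counts = counts, nLevels = ng,
                 nRoiVoxels = sum(grayLevels(roi) > 0L)), class = "gldzm")
}

#' Neighboring gray level dependence matrix
#'
#' The dependence count of a voxel is the number of its 26-neighbours inside
#' the ROI whose gray level differs by at most `alpha`; the centre voxel is
#' never counted, so dependence ranges over 0..26 (columns of the matrix).
#' Feature weights downstream use dependence + 1.
#'
#' @param roi A nonempty [DiscretizedRoi-class].
#' @param alpha Coarseness tolerance (gray levels), default 0.
#' @param distance Neighbourhood Chebyshev radius; only 1 is supported.
#' @return Object of class `ngldm`: `counts` (nLevels x 27), `nLevels`,
#'   `nRoiVoxels`.
#' @export
buildNgldm <- function(roi, alpha = 0L, distance = 1L) {
  stopifnot(is(roi, "DiscretizedRoi"), distance == 1L)
  if (!any(grayLevels(roi) > 0L)) stop("empty ROI")
  counts <- .cppNgldm(grayLevels(roi), nBins(roi), as.integer(alpha))
  structure(list(counts = counts, nLevels = nBins(roi),
                 nRoiVoxels = sum(grayLevels(roi) > 0L)), class = "ngldm")
}

#' Neighborhood gray tone difference matrix
#'
#' For each gray level i: the number of ROI voxels `n_i` of that level with
#' at least one ROI neighbour, and the summed absolute difference `s_i`
#' between the voxel level and the mean level of its in-ROI 26-neighbours.
#'
#' @param roi A nonempty [DiscretizedRoi-class].
#' @param distance Neighbourhood Chebyshev radius; only 1 is supported.
#' @return Object of class `ngtdm`: vectors `n` and `s` of length nLevels,
#'   plus `nLevels`, `nRoiVoxels`.
#' @export
buildNgtdm <- function(roi, distance = 1L) {
  stopifnot(is(roi, "DiscretizedRoi"), distance == 1L)
  if (!any(grayLevels(roi) > 0L)) stop("empty ROI")
  res <- .cppNgtdm(grayLevels(roi), nBins(roi))
  structure(list(n = res$n, s = res$s, nLevels = nBins(roi),
                 nRoiVoxels = sum(grayLevels(roi) > 0L)), class = "ngtdm")
}

#' Build all six texture matrices for a discretized ROI
#'
#' @param roi A [DiscretizedRoi-class].
#' @param glcmDistance GLCM voxel distance.
#' @param ngldmAlpha NGLDM coarseness tolerance.
#' @return Named list with elements glcm, glrlm, glszm, gldzm, ngldm, ngtdm.
#' @export
textureMatrices <- function(roi, glcmDistance = 1L, ngldmAlpha = 0L) {
  list(glcm = buildGlcm(roi, glcmDistance), glrlm = buildGlrlm(roi),
       glszm = buildGlszm(roi), gldzm = buildGldzm(roi),
       ngldm = buildNgldm(roi, ngldmAlpha), ngtdm = buildNgtdm(roi))
}
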