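## Volume preparation: NIfTI I/O, isotropic resampling, HU re-segmentation
## and fixed-bin-size gray-level discretization.

#' Read / write CT volumes and masks (NIfTI)
#'
#' Thin wrappers around RNifti. Volumes are HU arrays; masks are binarized
#' at > 0.5 on read. Voxel spacing is taken from the NIfTI pixdim.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @return [CTVolume-class] / [RoiMask-class].
#' @export
readVolume <- function(path) {
  im <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(im)[1:3]
  CTVolume(array(as.numeric(im), dim(im)[1:3]), spacing = sp)
}

#' @rdname readVolume
#' @export
readMask <- function(path) {
  im <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(im)[1:3]
  RoiMask(array(as.numeric(im) > 0.5, dim(im)[1:3]), spacing = sp)
}

#' @param vol A [CTVolume-class].
#' @rdname readVolume
#' @export
writeVolume <- function(vol, path) {
  im <- RNifti::asNifti(intensities(vol))
  RNifti::pixdim(im) <- voxelSpacing(vol)
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' @param mask A [RoiMask-class].
#' @rdname readVolume
#' @export
writeMask <- function(mask, path) {
  im <- RNifti::asNifti(array(as.integer(roiArray(mask)), dim(roiArray(mask))))
  RNifti::pixdim(im) <- voxelSpacing(mask)
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Merge lung masks by voxelwise OR
#'
#' Left and right lungs are delineated separately but analyzed as a single
#' organ; this merges any number of aligned masks.
#'
#' @param ... [RoiMask-class] objects on the same grid.
#' @return A single merged [RoiMask-class].
#' @export
mergeMasks <- function(...) {
  masks <- list(...)
  stopifnot(length(masks) >= 1L)
  ref <- masks[[1L]]
  out <- roiArray(ref)
  for (m in masks[-1L]) {
    if (!identical(dim(roiArray(m)), dim(out)))
      stop("mask geometry mismatch in mergeMasks")
    out <- out | roiArray(m)
  }
  RoiMask(out, voxelSpacing(ref), ref@origin)
}

# trilinear interpolation of array `a` at target grid defined by per-axis
# source-index coordinate vectors (1-based, clamped by caller)
trilinearGrid <- function(a, gx, gy, gz) {
  d <- dim(a)
  ix <- pmin(pmax(floor(gx), 1), max(d[1] - 1, 1)); fx <- pmin(pmax(gx - ix, 0), 1)
  iy <- pmin(pmax(floor(gy), 1), max(d[2] - 1, 1)); fy <- pmin(pmax(gy - iy, 0), 1)
  iz <- pmin(pmax(floor(gz), 1), max(d[3] - 1, 1)); fz <- pmin(pmax(gz - iz, 0), 1)
  nd <- c(length(gx), length(gy), length(gz))
  out <- array(0, nd)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wx <- if (dx) fx else 1 - fx
    wy <- if (dy) fy else 1 - fy
    wz <- if (dz) fz else 1 - fz
    w <- array(outer(outer(wx, wy), wz), nd)
    out <- out + w * a[pmin(ix + dx, d[1]), pmin(iy + dy, d[2]), pmin(iz + dz, d[3]),
                       drop = FALSE]
  }
  out
}

#' Resample a volume and its mask to isotropic resolution
#'
#' Trilinear interpolation for the image; the mask is linearly interpolated
#' and thresholded at 0.5 (avoids nearest-neighbour aliasing of thin lung
#' margins). Voxel centres of the output grid span the same physical extent;
#' the output voxel volume is exactly `targetMm^3`. If the input is already
#' isotropic at the target spacing both objects are returned unchanged.
#'
#' @param vol A [CTVolume-class].
#' @param mask A [RoiMask-class] on the same grid.
#' @param targetMm Positive scalar target spacing (mm).
#' @return `list(volume = CTVolume, mask = RoiMask)`.
#' @export
resampleIsotropic <- function(vol, mask, targetMm) {
  stopifnot(targetMm > 0)
  sp <- voxelSpacing(vol)
  if (!identical(dim(intensities(vol)), dim(roiArray(mask))))
    stop("volume/mask geometry mismatch")
  if (all(abs(sp - targetMm) < 1e-9)) return(list(volume = vol, mask = mask))
  d <- dim(intensities(vol))
  ndim <- pmax(2L, floor((d - 1) * sp / targetMm + 1e-9) + 1L)
  coord <- function(axis) (seq_len(ndim[axis]) - 1) * targetMm / sp[axis] + 1
  gx <- coord(1); gy <- coord(2); gz <- coord(3)
  newVol <- trilinearGrid(intensities(vol), gx, gy, gz)
  newMask <- trilinearGrid(array(as.numeric(roiArray(mask)), d), gx, gy, gz) >= 0.5
  if (!any(newMask)) stop("resampling produced an empty mask")
  list(volume = CTVolume(newVol, rep(targetMm, 3), vol@origin),
       mask = RoiMask(newMask, rep(targetMm, 3), mask@origin))
}

#' Re-segment a mask to an HU range
#'
#' Restricts the ROI to voxels whose intensity lies within `[low, high]`
#' (bounds inclusive); idempotent.
#'
#' @param vol A [CTVolume-class].
#' @param mask A [RoiMask-class] on the same grid.
#' @param low,high HU range, `low < high`. Defaults are the lung analysis
#'   window of -1000 to 200 HU.
#' @return The restricted [RoiMask-class].
#' @export
resegment <- function(vol, mask, low = -1000, high = 200) {
  stopifnot(low < high)
  if (!identical(dim(intensities(vol)), dim(roiArray(mask))))
    stop("volume/mask geometry mismatch")
  hu <- intensities(vol)
  out <- roiArray(mask) & hu >= low & hu <= high
  if (!any(out)) stop("re-segmentation produced an empty mask")
  RoiMask(out, voxelSpacing(mask), mask@origin)
}

#' Fixed-bin-size gray-level discretization
#'
#' Maps each ROI voxel to `floor((x - rangeLow) / binWidth) + 1`, with bins
#' anchored at the lower re-segmentation bound so levels are comparable
#' across subjects and domains. Bins are half-open `[edge, edge)` except the
#' last, which is closed: a voxel exactly at `rangeHigh` is clamped to the
#' top bin. The level count is derived from the full re-segmentation range
#' (24 levels for -1000..200 HU at 50 HU width), regardless of the values
#' actually present.
#'
#' @param vol A [CTVolume-class].
#' @param mask A re-segmented [RoiMask-class].
#' @param binWidth Bin width in HU (> 0).
#' @param rangeLow,rangeHigh Re-segmentation range the bins cover.
#' @return A [DiscretizedRoi-class].
#' @export
discretizeFBS <- function(vol, mask, binWidth = 50, rangeLow = -1000,
                          rangeHigh = 200) {
  stopifnot(binWidth > 0, rangeLow < rangeHigh)
  if (!identical(dim(intensities(vol)), dim(roiArray(mask))))
    stop("volume/mask geometry mismatch")
  hu <- intensities(vol)
  m <- roiArray(mask)
  x <- hu[m]
  if (any(x < rangeLow) || any(x > rangeHigh))
    stop("ROI voxels outside the discretization range; run resegment() first")
  nb <- as.integer(ceiling((rangeHigh - rangeLow) / binWidth - 1e-9))
  lev <- pmin(as.integer(floor((x - rangeLow) / binWidth)) + 1L, nb)
  out <- array(0L, dim(hu))
  out[m] <- lev
  new("DiscretizedRoi", levels = out, nBins = nb, binWidth = binWidth,
      rangeHU = c(rangeLow, rangeHigh), spacing = voxelSpacing(vol))
}
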