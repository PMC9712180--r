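#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
NULL

## ---------------------------------------------------------------------------
## CTVolume / RoiMask / DiscretizedRoi
## ---------------------------------------------------------------------------

#' CT volume in Hounsfield units
#'
#' A 3D scalar grid of CT attenuation values (HU) with anisotropic voxel
#' spacing in millimetres and a world-space origin.
#'
#' @slot intensities 3D numeric array of HU values.
#' @slot spacing Positive numeric(3), voxel spacing in mm per axis.
#' @slot origin Numeric(3), world coordinate of the first voxel centre.
#' @export
setClass("CTVolume",
  representation(intensities = "array", spacing = "numeric", origin = "numeric"))

setValidity("CTVolume", function(object) {
  if (length(dim(object@intensities)) != 3L) return("intensities must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0)) return("spacing must be positive numeric(3)")
  if (length(object@origin) != 3L) return("origin must be numeric(3)")
  if (any(!is.finite(object@intensities))) return("intensities must be finite")
  TRUE
})

#' @param intensities 3D numeric array of HU values.
#' @param spacing Positive numeric(3), mm.
#' @param origin Numeric(3) world origin, default `c(0, 0, 0)`.
#' @rdname CTVolume-class
#' @export
CTVolume <- function(intensities, spacing, origin = c(0, 0, 0)) {
  new("CTVolume", intensities = intensities, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Binary lung mask aligned to a CT volume
#'
#' @slot mask 3D logical array (same grid as its volume).
#' @slot spacing Positive numeric(3), mm.
#' @slot origin Numeric(3).
#' @export
setClass("RoiMask",
  representation(mask = "array", spacing = "numeric", origin = "numeric"))

setValidity("RoiMask", function(object) {
  if (length(dim(object@mask)) != 3L) return("mask must be a 3D array")
  if (!is.logical(object@mask)) return("mask must be logical")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be positive numeric(3)")
  TRUE
})

#' @param mask 3D logical (or 0/1) array.
#' @param spacing Positive numeric(3), mm.
#' @param origin Numeric(3) world origin.
#' @rdname RoiMask-class
#' @export
RoiMask <- function(mask, spacing, origin = c(0, 0, 0)) {
  m <- array(as.logical(mask), dim = dim(mask))
  new("RoiMask", mask = m, spacing = as.numeric(spacing), origin = as.numeric(origin))
}

#' Discretized ROI gray-level grid
#'
#' Integer gray levels over the re-segmented ROI (fixed bin size), with 0 as
#' the background sentinel outside the ROI.
#'
#' @slot levels 3D integer array; 0 outside the ROI, 1..nBins inside.
#' @slot nBins Number of gray levels spanned by the re-segmentation range.
#' @slot binWidth Bin width in HU.
#' @slot rangeHU Numeric(2), the re-segmentation range the bins cover.
#' @slot spacing Positive numeric(3), mm.
#' @export
setClass("DiscretizedRoi",
  representation(levels = "array", nBins = "integer", binWidth = "numeric",
                 rangeHU = "numeric", spacing = "numeric"))

setValidity("DiscretizedRoi", function(object) {
  lv <- object@levels
  if (length(dim(lv)) != 3L || !is.integer(lv)) return("levels must be a 3D integer array")
  inroi <- lv[lv > 0L]
  if (length(inroi) && max(inroi) > object@nBins)
    return("gray levels exceed nBins")
  if (object@nBins < 1L) return("nBins must be >= 1")
  TRUE
})

## ---------------------------------------------------------------------------
## Accessor generics
## ---------------------------------------------------------------------------

#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @export
setGeneric("roiArray", function(x) standardGeneric("roiArray"))
#' @export
setGeneric("grayLevels", function(x) standardGeneric("grayLevels"))
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' @describeIn CTVolume-class HU array accessor.
#' @export
setMethod("intensities", "CTVolume", function(x) x@intensities)
#' @describeIn CTVolume-class voxel spacing (mm) accessor.
#' @export
setMethod("voxelSpacing", "CTVolume", function(x) x@spacing)
#' @describeIn RoiMask-class logical array accessor.
#' @export
setMethod("roiArray", "RoiMask", function(x) x@mask)
#' @describeIn RoiMask-class voxel spacing (mm) accessor.
#' @export
setMethod("voxelSpacing", "RoiMask", function(x) x@spacing)
#' @describeIn DiscretizedRoi-class gray-level array accessor (0 = background).
#' @export
setMethod("grayLevels", "DiscretizedRoi", function(x) x@levels)
#' @describeIn DiscretizedRoi-class number of gray levels.
#' @export
setMethod("nBins", "DiscretizedRoi", function(x) x@nBins)
#' @describeIn DiscretizedRoi-class bin width in HU.
#' @export
setMethod("binWidth", "DiscretizedRoi", function(x) x@binWidth)
#' @describeIn DiscretizedRoi-class voxel spacing (mm) accessor.
#' @export
setMethod("voxelSpacing", "DiscretizedRoi", function(x) x@spacing)

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@intensities)
  cat("CTVolume:", paste(d, collapse = " x "), "voxels, spacing",
      paste(signif(object@spacing, 4), collapse = " x "), "mm\n")
  cat("  HU range: [", round(min(object@intensities), 1), ",",
      round(max(object@intensities), 1), "]\n")
})

setMethod("show", "RoiMask", function(object) {
  cat("RoiMask:", paste(dim(object@mask), collapse = " x "), "voxels,",
      sum(object@mask), "in ROI\n")
})

setMethod("show", "DiscretizedRoi", function(object) {
  cat("DiscretizedRoi:", sum(object@levels > 0L), "ROI voxels,",
      object@nBins, "gray levels (bin width", object@binWidth, "HU)\n")
})

## ---------------------------------------------------------------------------
## RadiomicsFeatureSet
## ---------------------------------------------------------------------------

#' Radiomic feature table as a SummarizedExperiment
#'
#' Rows are radiomic features (V-codes), columns are scans: one column per
#' (subject, observer, repetition) combination. `rowData` carries the feature
#' family; `colData` carries subject, domain, label, observer and repetition.
#' Observer 0 / repetition 0 denotes the reference delineation; observers
#' >= 1 mark delineation-stability scans.
#'
#' @export
setClass("RadiomicsFeatureSet", contains = "SummarizedExperiment")

setValidity("RadiomicsFeatureSet", function(object) {
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    return("assay 'features' is required")
  need <- c("subject", "domain", "label", "observer", "repetition")
  miss <- setdiff(need, colnames(SummarizedExperiment::colData(object)))
  if (length(miss)) return(paste("missing colData columns:", paste(miss, collapse = ", ")))
  if (!"family" %in% colnames(SummarizedExperiment::rowData(object)))
    return("rowData must carry a 'family' column")
  if (anyNA(SummarizedExperiment::assay(object, "features")))
    return("feature values must not be missing")
  TRUE
})

#' Construct a RadiomicsFeatureSet
#'
#' @param values Numeric matrix, features x scans; rownames are feature ids.
#' @param sampleInfo data.frame with columns subject, domain, label, observer,
#'   repetition (one row per column of `values`).
#' @param family Character vector of feature families, one per row of
#'   `values`; defaults to the registry families when ids are V-codes.
#' @return A [RadiomicsFeatureSet-class] object.
#' @export
RadiomicsFeatureSet <- function(values, sampleInfo, family = NULL) {
  values <- as.matrix(values)
  if (is.null(family)) {
    reg <- featureRegistry()
    family <- reg$family[match(rownames(values), reg$id)]
    if (anyNA(family)) family[is.na(family)] <- "OTHER"
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = values),
    rowData = S4Vectors::DataFrame(family = family, row.names = rownames(values)),
    colData = S4Vectors::DataFrame(sampleInfo))
  new("RadiomicsFeatureSet", se)
}

#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @export
setGeneric("featureFamilies", function(x) standardGeneric("featureFamilies"))

#' @describeIn RadiomicsFeatureSet-class feature matrix (features x scans).
#' @export
setMethod("featureValues", "RadiomicsFeatureSet",
  function(x) SummarizedExperiment::assay(x, "features"))
#' @describeIn RadiomicsFeatureSet-class named vector of feature families.
#' @export
setMethod("featureFamilies", "RadiomicsFeatureSet", function(x)
  stats::setNames(SummarizedExperiment::rowData(x)$family, rownames(x)))

setMethod("show", "RadiomicsFeatureSet", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("RadiomicsFeatureSet:", nrow(object), "features x", ncol(object), "scans\n")
  cat("  domains:", paste(unique(cd$domain), collapse = ", "),
      "| labels:", paste(unique(cd$label), collapse = ", "), "\n")
  cat("  reference scans:", sum(cd$observer == 0),
      "| stability scans:", sum(cd$observer > 0), "\n")
})

# scans x features matrix + labels for the reference delineations only
referenceXY <- function(fs, domain = NULL) {
  stopifnot(is(fs, "RadiomicsFeatureSet"))
  cd <- SummarizedExperiment::colData(fs)
  keep <- cd$observer == 0
  if (!is.null(domain)) keep <- keep & cd$domain == domain
  if (!any(keep)) stop("no reference scans", if (!is.null(domain)) paste0(" in domain '", domain, "'"))
  list(x = t(SummarizedExperiment::assay(fs, "features")[, keep, drop = FALSE]),
       y = as.character(cd$label[keep]),
       subject = as.character(cd$subject[keep]))
}
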