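## Subject-level feature extraction: resample -> re-segment -> histogram
## features on raw HU -> fixed-bin-size discretization -> texture matrices
## -> 137 texture features. Output is the named 154-feature vector.

#' Extraction configuration
#'
#' @param targetSpacingMm Isotropic resampling target in mm, either a single
#'   number or a named list/vector with one entry per domain
#'   (e.g. `c(microct = 0.2, hrct = 1.0)`). `NA` skips resampling.
#' @param huRange Numeric(2) re-segmentation window (inclusive).
#' @param binWidthHu Fixed bin size in HU.
#' @param glcmDistance GLCM voxel distance.
#' @param ngldmAlpha NGLDM coarseness tolerance.
#' @return A list of class `extractionConfig`.
#' @export
extractionConfig <- function(targetSpacingMm = c(microct = 0.2, hrct = 1.0),
                             huRange = c(-1000, 200), binWidthHu = 50,
                             glcmDistance = 1L, ngldmAlpha = 0L) {
  stopifnot(length(huRange) == 2L, huRange[1] < huRange[2], binWidthHu > 0)
  structure(list(targetSpacingMm = targetSpacingMm, huRange = huRange,
                 binWidthHu = binWidthHu, glcmDistance = as.integer(glcmDistance),
                 ngldmAlpha = as.integer(ngldmAlpha)),
            class = "extractionConfig")
}

targetSpacingFor <- function(config, domain) {
  ts <- config$targetSpacingMm
  if (length(ts) > 1L || !is.null(names(ts))) {
    if (!domain %in% names(ts)) stop("no target spacing configured for domain ", domain)
    ts <- ts[[domain]]
  }
  ts
}

#' Compute the 154-feature radiomic signature of one subject
#'
#' @param vol A [CTVolume-class].
#' @param mask A [RoiMask-class] aligned to `vol` (merged lungs).
#' @param config An [extractionConfig()].
#' @param domain Domain tag used to pick the resampling target.
#' @return Named numeric vector of length 154 (V1..V154).
#' @export
computeFeatures <- function(vol, mask, config = extractionConfig(),
                            domain = "microct") {
  if (!identical(dim(intensities(vol)), dim(roiArray(mask))))
    stop("volume/mask geometry mismatch")
  ts <- targetSpacingFor(config, domain)
  if (!is.na(ts)) {
    rs <- resampleIsotropic(vol, mask, ts)
    vol <- rs$volume
    mask <- rs$mask
  }
  mask <- resegment(vol, mask, config$huRange[1], config$huRange[2])
  hist <- histogramFeatures(vol, mask)
  roi <- discretizeFBS(vol, mask, config$binWidthHu,
                       config$huRange[1], config$huRange[2])
  tex <- textureFeatures(textureMatrices(roi, config$glcmDistance,
                                         config$ngldmAlpha))
  reg <- featureRegistry()
  out <- c(hist, tex)
  stopifnot(length(out) == 154L)
  names(out) <- reg$id
  out
}

#' Extract features for a whole cohort manifest
#'
#' Reads each volume/mask pair listed in the manifest, runs the extraction
#' chain and assembles a [RadiomicsFeatureSet-class]. Any subject failing
#' preprocessing aborts the run with the subject named — rows are never
#' silently dropped.
#'
#' @param manifest data.frame with columns subject_id, domain, label,
#'   observer, `repeat`, volume_path, mask_path (as written by
#'   [generateCohort()]), or the path of such a CSV.
#' @param config An [extractionConfig()].
#' @param verbose Log one line per scan with its ROI voxel count.
#' @return A [RadiomicsFeatureSet-class] with one column per manifest row.
#' @export
extractAll <- function(manifest, config = extractionConfig(), verbose = FALSE) {
  if (is.character(manifest))
    manifest <- utils::read.csv(manifest, check.names = FALSE,
                                stringsAsFactors = FALSE)
  need <- c("subject_id", "domain", "label", "observer", "repeat",
            "volume_path", "mask_path")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) stop("manifest lacks columns: ", paste(miss, collapse = ", "))
  reg <- featureRegistry()
  vals <- matrix(NA_real_, nrow(reg), nrow(manifest),
                 dimnames = list(reg$id, NULL))
  volCache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$subject_id[i]
    vp <- manifest$volume_path[i]
    vol <- if (!is.null(volCache[[vp]])) volCache[[vp]] else {
      v <- readVolume(vp); volCache[[vp]] <- v; v
    }
    mask <- readMask(manifest$mask_path[i])
    feats <- tryCatch(
      computeFeatures(vol, mask, config, domain = manifest$domain[i]),
      error = function(e) stop("extraction failed for subject '", sid, "': ",
                               conditionMessage(e), call. = FALSE))
    if (verbose)
      message(sprintf("%s (obs %s, rep %s): %d ROI voxels", sid,
                      manifest$observer[i], manifest$`repeat`[i],
                      sum(roiArray(mask))))
    vals[, i] <- feats
  }
  RadiomicsFeatureSet(vals, data.frame(
    subject = manifest$subject_id, domain = manifest$domain,
    label = manifest$label, observer = as.integer(manifest$observer),
    repetition = as.integer(manifest$`repeat`), stringsAsFactors = FALSE))
}

#' Write a feature set to CSV (+ JSON registry sidecar)
#'
#' @param fs A [RadiomicsFeatureSet-class].
#' @param path Output CSV path; the registry goes to `<path>_registry.json`.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(fs, path) {
  cd <- as.data.frame(SummarizedExperiment::colData(fs))
  tab <- cbind(cd, as.data.frame(t(featureValues(fs))))
  utils::write.csv(tab, path, row.names = FALSE)
  jsonlite::write_json(featureRegistry(),
                       sub("\\.csv$", "_registry.json", path),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(path)
}
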