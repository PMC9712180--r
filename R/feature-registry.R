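## Declarative registry of the 154-feature signature. The registry fixes the
## V-code order; the anchors V1 (mean), V2 (SD), V4 (skewness), V5
## (kurtosis), V16 (RMS), V108 (GLSZM gray level non-uniformity normalized)
## and V141 (NGLDM dependence count non-uniformity) are pinned by the
## ordering below. Math code looks features up by name, so the registry can
## be swapped without touching formulas.

histFeatureNames <- function() c(
  "mean", "sd", "median", "skewness", "kurtosis", "min", "p10", "p90",
  "max", "iqr", "range", "meanAbsDev", "robustMeanAbsDev", "medianAbsDev",
  "coeffVariation", "rms", "energy")

glcmFeatureNames <- function() c(
  "jointMax", "jointAverage", "jointVariance", "jointEntropy",
  "diffAverage", "diffVariance", "diffEntropy",
  "sumAverage", "sumVariance", "sumEntropy",
  "angularSecondMoment", "contrast", "dissimilarity",
  "inverseDifference", "inverseDifferenceNorm",
  "inverseDifferenceMoment", "inverseDifferenceMomentNorm",
  "inverseVariance", "correlation", "autocorrelation",
  "clusterTendency", "clusterShade", "clusterProminence",
  "infoCorr1", "infoCorr2", "maxCorrCoeff")

# shared 16-feature scheme for run/zone/distance/dependence families;
# `small`/`large` refer to the column attribute (run length, zone size,
# zone distance, dependence count). Position 7 is the normalized gray level
# non-uniformity and position 8 the column-attribute non-uniformity.
rzFeatureNames <- function(kind) {
  k <- kind  # e.g. "run", "zoneSize", "zoneDist", "depCount"
  c(paste0("small", toupper(substr(k, 1, 1)), substr(k, 2, 99), "Emphasis"),
    paste0("large", toupper(substr(k, 1, 1)), substr(k, 2, 99), "Emphasis"),
    "lowGrayLevelEmphasis", "highGrayLevelEmphasis",
    paste0(k, "Percentage"),
    "grayLevelNonUniformity", "grayLevelNonUniformityNorm",
    paste0(k, "NonUniformity"), paste0(k, "NonUniformityNorm"),
    "smallLowGrayLevelEmphasis", "smallHighGrayLevelEmphasis",
    "largeLowGrayLevelEmphasis", "largeHighGrayLevelEmphasis",
    "grayLevelVariance", paste0(k, "Variance"), paste0(k, "Entropy"))
}

ngtdmFeatureNames <- function() c(
  "coarseness", "contrast", "busyness", "complexity", "strength")

#' The 154-feature registry
#'
#' @return data.frame with columns `id` (V1..V154), `family` (HIST,
#'   GLCM_avg, GLCM_merged, GLRLM_avg, GLRLM_merged, GLSZM, GLDZM, NGLDM,
#'   NGTDM) and `name`.
#' @export
featureRegistry <- function() {
  reg <- rbind(
    data.frame(family = "HIST", name = histFeatureNames()),
    data.frame(family = "GLCM_avg", name = glcmFeatureNames()),
    data.frame(family = "GLCM_merged", name = glcmFeatureNames()),
    data.frame(family = "GLRLM_avg", name = rzFeatureNames("run")),
    data.frame(family = "GLRLM_merged", name = rzFeatureNames("run")),
    data.frame(family = "GLSZM", name = rzFeatureNames("zoneSize")),
    data.frame(family = "GLDZM", name = rzFeatureNames("zoneDist")),
    data.frame(family = "NGLDM", name = rzFeatureNames("depCount")),
    data.frame(family = "NGTDM", name = ngtdmFeatureNames()))
  counts <- c(HIST = 17L, GLCM_avg = 26L, GLCM_merged = 26L, GLRLM_avg = 16L,
              GLRLM_merged = 16L, GLSZM = 16L, GLDZM = 16L, NGLDM = 16L,
              NGTDM = 5L)
  got <- table(factor(reg$family, levels = names(counts)))
  stopifnot(identical(as.integer(got), as.integer(counts)), nrow(reg) == 154L)
  anchors <- c(V1 = "mean", V2 = "sd", V4 = "skewness", V5 = "kurtosis",
               V16 = "rms", V108 = "grayLevelNonUniformityNorm",
               V141 = "depCountNonUniformity")
  reg$id <- paste0("V", seq_len(nrow(reg)))
  stopifnot(identical(reg$name[match(names(anchors), reg$id)],
                      unname(anchors)))
  reg[, c("id", "family", "name")]
}
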