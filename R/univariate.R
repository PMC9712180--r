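## Univariate screening: directional AUC per feature and domain, and the
## cross-domain correlation of discriminative power.

#' Directional AUC (Mann-Whitney convention)
#'
#' `auc` is the probability that a value drawn from the positive class
#' exceeds a value drawn from the negative class, with ties credited 0.5
#' (mid-rank). Values below 0.5 are *not* flipped: the direction of the
#' effect is part of the result, so that e.g. 0.3 in one domain and 0.7 in
#' the other signal opposite trends of the same magnitude.
#'
#' @param values Numeric vector of per-subject feature values.
#' @param labels Class labels aligned with `values`.
#' @param positive Label of the positive class (default `"ild"`).
#' @return List with `auc`, `nPos`, `nNeg`.
#' @export
directionalAuc <- function(values, labels, positive = "ild") {
  stopifnot(length(values) == length(labels))
  pos <- labels == positive
  nPos <- sum(pos)
  nNeg <- sum(!pos)
  if (nPos == 0L || nNeg == 0L) stop("both classes must be nonempty")
  r <- rank(values)                      # mid-ranks handle ties
  u <- sum(r[pos]) - nPos * (nPos + 1) / 2
  list(auc = u / (nPos * nNeg), nPos = nPos, nNeg = nNeg)
}

#' Per-feature directional AUC table
#'
#' @param fs A [RadiomicsFeatureSet-class]; only reference scans
#'   (observer 0) are used.
#' @param features Feature ids to evaluate (default all).
#' @param positive Positive class label.
#' @return data.frame with feature, family, domain, auc, nPos, nNeg.
#' @export
aucTable <- function(fs, features = rownames(fs), positive = "ild") {
  cd <- SummarizedExperiment::colData(fs)
  fam <- featureFamilies(fs)
  out <- list()
  for (dom in unique(as.character(cd$domain))) {
    xy <- referenceXY(fs, dom)
    for (f in features) {
      a <- directionalAuc(xy$x[, f], xy$y, positive)
      out[[length(out) + 1L]] <- data.frame(
        feature = f, family = unname(fam[f]), domain = dom,
        auc = a$auc, nPos = a$nPos, nNeg = a$nNeg, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Cross-domain correlation of feature discriminative power
#'
#' Pearson correlation between the per-feature directional AUCs of two
#' domains, overall and per feature family.
#'
#' @param aucA,aucB Named numeric vectors of AUCs (names = feature ids) or
#'   data.frames as returned by [aucTable()] (single domain each).
#' @param families Optional named family vector for the per-family split.
#' @return List with `r` (overall Pearson r), `n` (matched features), and
#'   `byFamily` data.frame; plus the matched `scatter` data.
#' @export
crossDomainCorrelation <- function(aucA, aucB, families = NULL) {
  toVec <- function(a) {
    if (is.data.frame(a)) stats::setNames(a$auc, a$feature) else a
  }
  va <- toVec(aucA)
  vb <- toVec(aucB)
  ids <- intersect(names(va), names(vb))
  if (length(ids) < 3L) stop("need at least 3 matched features")
  if (is.null(families) && is.data.frame(aucA))
    families <- stats::setNames(aucA$family, aucA$feature)
  r <- stats::cor(va[ids], vb[ids])
  byFamily <- NULL
  if (!is.null(families)) {
    famSplit <- split(ids, families[ids])
    byFamily <- data.frame(
      family = names(famSplit),
      n = vapply(famSplit, length, integer(1)),
      r = vapply(famSplit, function(k)
        if (length(k) >= 3 && stats::sd(va[k]) > 0 && stats::sd(vb[k]) > 0)
          stats::cor(va[k], vb[k]) else NA_real_, numeric(1)),
      row.names = NULL)
  }
  list(r = r, n = length(ids), byFamily = byFamily,
       scatter = data.frame(feature = ids, aucA = unname(va[ids]),
                            aucB = unname(vb[ids])))
}
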