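## Delineation-stability analysis: two-way consistency intraclass
## correlation, the four-cell (setting x domain) stability filter, and the
## averaged-vs-merged aggregation redundancy check.

#' Consistency intraclass correlation, ICC(3,1)
#'
#' Two-way mixed-effects, single-rater, consistency ICC from the two-way
#' ANOVA decomposition: `(MS_R - MS_E) / (MS_R + (k - 1) MS_E)` with
#' `MS_R` the between-subject and `MS_E` the residual mean square of a
#' subjects x raters layout. Consistency ICC ignores additive rater bias.
#' The one-way variant ICC(1,1) is also available.
#'
#' @param ratings Numeric matrix, subjects x raters (>= 2 each, no missing
#'   cells).
#' @param variant `"ICC31"` (default, two-way consistency) or `"ICC11"`
#'   (one-way absolute agreement).
#' @return List with `icc` (NA when between-subject variance is zero —
#'   flagged `undefined` and treated as unstable downstream), `msBetween`,
#'   `msError`.
#' @export
iccConsistency <- function(ratings, variant = c("ICC31", "ICC11")) {
  variant <- match.arg(variant)
  ratings <- as.matrix(ratings)
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 raters")
  if (anyNA(ratings)) stop("missing cells are not allowed")
  grand <- mean(ratings)
  rowM <- rowMeans(ratings)
  colM <- colMeans(ratings)
  ssTotal <- sum((ratings - grand)^2)
  ssRows <- k * sum((rowM - grand)^2)
  ssCols <- n * sum((colM - grand)^2)
  msRows <- ssRows / (n - 1)
  if (variant == "ICC31") {
    ssErr <- ssTotal - ssRows - ssCols
    msErr <- ssErr / ((n - 1) * (k - 1))
    den <- msRows + (k - 1) * msErr
  } else {
    ssErr <- ssTotal - ssRows            # one-way: columns pooled into error
    msErr <- ssErr / (n * (k - 1))
    den <- msRows + (k - 1) * msErr
  }
  # all ratings identical (no subject signal, no rater noise): perfect
  # agreement. Zero between-subject variance with nonzero noise: undefined,
  # treated as unstable downstream.
  if (ssTotal <= 1e-20 * max(1, grand^2)) {
    return(list(icc = 1, msBetween = msRows, msError = msErr,
                undefined = FALSE))
  }
  undefined <- msRows <= 1e-12 * (ssTotal / (n - 1)) || den <= 0
  icc <- if (undefined) NA_real_ else (msRows - msErr) / den
  list(icc = icc, msBetween = msRows, msError = msErr, undefined = undefined)
}

# subjects x raters matrix of one feature for one (domain, setting) cell
stabilityCell <- function(fs, feature, domain, setting = c("intra", "inter")) {
  setting <- match.arg(setting)
  cd <- SummarizedExperiment::colData(fs)
  vals <- featureValues(fs)[feature, ]
  sel <- cd$domain == domain & cd$observer > 0
  if (setting == "intra") {
    sel <- sel & cd$observer == 1
    rater <- cd$repetition
  } else {
    sel <- sel & cd$repetition == 1
    rater <- cd$observer
  }
  if (!any(sel)) stop("no ", setting, "observer scans for domain '", domain, "'")
  d <- data.frame(subject = cd$subject[sel], rater = rater[sel],
                  value = vals[sel])
  wide <- stats::reshape(d, idvar = "subject", timevar = "rater",
                         direction = "wide")
  m <- as.matrix(wide[, -1, drop = FALSE])
  if (anyNA(m) || ncol(m) < 2L)
    stop("incomplete ", setting, "observer stability cell for domain '", domain, "'")
  m
}

#' Filter features by delineation stability
#'
#' A feature is retained iff its consistency ICC reaches `threshold` in all
#' four cells: intra- and interobserver settings in both domains. Undefined
#' ICCs (zero between-subject variance) count as unstable.
#'
#' @param fs A [RadiomicsFeatureSet-class] containing stability scans
#'   (observer >= 1) for both domains.
#' @param threshold Stability threshold, default 0.75.
#' @param variant ICC variant, see [iccConsistency()].
#' @return List with `retained` (feature ids), `icc` (per-feature per-cell
#'   table) and `familySummary` (per-family unstable proportions).
#' @export
stabilityFilter <- function(fs, threshold = 0.75, variant = "ICC31") {
  cd <- SummarizedExperiment::colData(fs)
  domains <- unique(as.character(cd$domain))
  if (!any(cd$observer > 0)) stop("no stability scans present")
  feats <- rownames(fs)
  cells <- expand.grid(domain = domains, setting = c("intra", "inter"),
                       stringsAsFactors = FALSE)
  iccTab <- data.frame(feature = feats,
                       family = as.character(featureFamilies(fs)),
                       stringsAsFactors = FALSE)
  for (ci in seq_len(nrow(cells))) {
    col <- paste0("icc_", cells$setting[ci], "_", cells$domain[ci])
    iccTab[[col]] <- vapply(feats, function(f) {
      m <- stabilityCell(fs, f, cells$domain[ci], cells$setting[ci])
      iccConsistency(m, variant)$icc
    }, numeric(1))
  }
  iccCols <- grep("^icc_", names(iccTab))
  stable <- apply(iccTab[, iccCols, drop = FALSE], 1,
                  function(r) all(!is.na(r) & r >= threshold))
  iccTab$stable <- stable
  fam <- split(stable, iccTab$family)
  familySummary <- data.frame(
    family = names(fam),
    nFeatures = vapply(fam, length, integer(1)),
    unstableFraction = vapply(fam, function(s) mean(!s), numeric(1)),
    row.names = NULL)
  list(retained = feats[stable], icc = iccTab, familySummary = familySummary)
}

#' Redundancy of averaged vs merged directional aggregation
#'
#' For GLCM and GLRLM the signature carries each feature under both
#' directional aggregations. Per family, paired feature values (averaged,
#' merged) are z-scored per feature across reference scans, stacked, and
#' compared with a two-rater consistency ICC. When the ICC reaches
#' `threshold`, the merged variants are flagged redundant and dropped from
#' downstream analysis (the averaged variant is kept).
#'
#' @param fs A [RadiomicsFeatureSet-class].
#' @param threshold Redundancy ICC threshold, default 0.8.
#' @param drop If `FALSE`, nothing is dropped regardless of the ICC.
#' @return List with `icc` (per family), `dropped` (feature ids), and
#'   `kept` (all remaining feature ids).
#' @export
aggregationRedundancy <- function(fs, threshold = 0.8, drop = TRUE) {
  cd <- SummarizedExperiment::colData(fs)
  ref <- cd$observer == 0
  vals <- featureValues(fs)[, ref, drop = FALSE]
  fam <- featureFamilies(fs)
  icc <- c(GLCM = NA_real_, GLRLM = NA_real_)
  dropped <- character(0)
  for (fmly in c("GLCM", "GLRLM")) {
    avgIds <- names(fam)[fam == paste0(fmly, "_avg")]
    mrgIds <- names(fam)[fam == paste0(fmly, "_merged")]
    if (!length(avgIds) || length(avgIds) != length(mrgIds)) next
    pairs <- lapply(seq_along(avgIds), function(j) {
      a <- vals[avgIds[j], ]
      b <- vals[mrgIds[j], ]
      mu <- mean(c(a, b))
      sdev <- stats::sd(c(a, b))
      if (sdev == 0) sdev <- 1
      cbind((a - mu) / sdev, (b - mu) / sdev)   # per-feature z-scoring
    })
    m <- do.call(rbind, pairs)
    icc[fmly] <- iccConsistency(m)$icc
    if (isTRUE(drop) && !is.na(icc[fmly]) && icc[fmly] >= threshold)
      dropped <- c(dropped, mrgIds)
  }
  list(icc = icc, dropped = dropped, kept = setdiff(rownames(fs), dropped))
}
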