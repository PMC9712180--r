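## MEAN / MSSK / ML classifiers with nested cross-validated feature
## selection, domain transfer, target-domain re-optimization and Youden
## threshold diagnostics.
##
## MEAN uses the histogram mean (V1) only; MSSK the first four moments
## (V1 mean, V2 SD, V4 skewness, V5 kurtosis); ML runs, inside every CV
## fold, correlation pruning at a sampled threshold, an L1-logistic
## selector whose path entry order ranks features, top-k retention, and a
## ridge-penalized logistic final classifier. Hyperparameters (correlation
## threshold, k, ridge strength) are drawn as randomized samples and scored
## by mean CV AUC. Standardization statistics always come from the training
## fold only; target-domain data never influences source tuning.

#' Model specification
#'
#' @slot architecture `"MEAN"`, `"MSSK"` or `"ML"`.
#' @slot corThresholdGrid Candidate correlation-pruning thresholds.
#' @slot kRange Integer(2): range of the number of selected features.
#' @slot lambdaRange Numeric(2): log-uniform ridge-strength range.
#' @slot nSamples Randomized hyperparameter samples (ML only).
#' @slot cvRepeats,cvFolds Cross-validation layout (default 4 x 5).
#' @slot seed Integer seed.
#' @export
setClass("ModelSpec",
  representation(architecture = "character", corThresholdGrid = "numeric",
    kRange = "integer", lambdaRange = "numeric", nSamples = "integer",
    cvRepeats = "integer", cvFolds = "integer", seed = "integer"))

setValidity("ModelSpec", function(object) {
  if (!object@architecture %in% c("MEAN", "MSSK", "ML"))
    return("architecture must be MEAN, MSSK or ML")
  if (any(object@corThresholdGrid <= 0 | object@corThresholdGrid > 1))
    return("corThresholdGrid must lie in (0, 1]")
  if (object@kRange[1] < 1L) return("kRange must start at >= 1")
  if (any(object@lambdaRange <= 0)) return("lambdaRange must be positive")
  TRUE
})

#' @param architecture `"MEAN"`, `"MSSK"` or `"ML"`.
#' @param corThresholdGrid,kRange,lambdaRange ML hyperparameter space.
#' @param nSamples Randomized hyperparameter samples.
#' @param cvRepeats,cvFolds CV layout.
#' @param seed Integer seed.
#' @rdname ModelSpec-class
#' @export
modelSpec <- function(architecture = c("ML", "MEAN", "MSSK"),
                      corThresholdGrid = seq(0.60, 0.99, by = 0.01),
                      kRange = c(1L, 10L), lambdaRange = c(1e-3, 1e3),
                      nSamples = 500L, cvRepeats = 4L, cvFolds = 5L,
                      seed = 1L) {
  new("ModelSpec", architecture = match.arg(architecture),
      corThresholdGrid = corThresholdGrid, kRange = as.integer(kRange),
      lambdaRange = lambdaRange, nSamples = as.integer(nSamples),
      cvRepeats = as.integer(cvRepeats), cvFolds = as.integer(cvFolds),
      seed = as.integer(seed))
}

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec:", object@architecture, "|", object@cvRepeats, "x",
      object@cvFolds, "CV")
  if (object@architecture == "ML")
    cat(" |", object@nSamples, "hyperparameter samples")
  cat("\n")
})

fixedFeaturesFor <- function(architecture) {
  switch(architecture,
         MEAN = "V1",
         MSSK = c("V1", "V2", "V4", "V5"),
         NULL)
}

## ---------------------------------------------------------------------------
## internals
## ---------------------------------------------------------------------------

# coerce a RadiomicsFeatureSet (reference scans of one domain) or an
# (x, y) list to the modeling representation
asXY <- function(data, domain = NULL, positive = "ild") {
  if (is(data, "RadiomicsFeatureSet")) {
    cd <- SummarizedExperiment::colData(data)
    doms <- unique(as.character(cd$domain))
    if (is.null(domain)) {
      if (length(doms) > 1L)
        stop("feature set spans domains ", paste(doms, collapse = ", "),
             "; pick one with `domain =`")
      domain <- doms
    }
    xy <- referenceXY(data, domain)
    list(x = xy$x, y = xy$y, positive = positive)
  } else {
    stopifnot(is.list(data), !is.null(data$x), !is.null(data$y))
    list(x = as.matrix(data$x), y = as.character(data$y), positive = positive)
  }
}

# stratified validation folds: list of index vectors, repeats x folds
makeFolds <- function(y, nFolds, nRepeats, seed) {
  withSeed(seed, {
    out <- list()
    for (r in seq_len(nRepeats)) {
      fold <- integer(length(y))
      for (cls in unique(y)) {
        idx <- sample(which(y == cls))
        fold[idx] <- rep(seq_len(nFolds), length.out = length(idx))
      }
      for (f in seq_len(nFolds)) out[[length(out) + 1L]] <- which(fold == f)
    }
    out
  })
}

# ridge-penalized logistic regression by IRLS; intercept unpenalized;
# iteration-capped so (quasi-)separable fits stay finite and deterministic
ridgeLogit <- function(X, y01, lambda, maxit = 30L, tol = 1e-8) {
  X <- as.matrix(X)
  p <- ncol(X)
  Xa <- cbind(1, X)
  beta <- numeric(p + 1)
  pen <- diag(c(0, rep(lambda, p)), p + 1, p + 1)
  for (it in seq_len(maxit)) {
    eta <- drop(Xa %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-6)
    z <- eta + (y01 - mu) / w
    H <- crossprod(Xa, Xa * w) + pen
    newBeta <- tryCatch(drop(solve(H, crossprod(Xa, w * z))),
                        error = function(e) beta)
    if (max(abs(newBeta - beta)) < tol) { beta <- newBeta; break }
    beta <- newBeta
  }
  list(intercept = beta[1], beta = stats::setNames(beta[-1], colnames(X)))
}

# greedy correlation pruning: features ranked by univariate separation
# (|AUC - 0.5|), a feature is kept iff |r| <= thr against everything
# already kept — of a correlated pair, the more discriminative one survives
pruneCorrelated <- function(corMat, score, thr) {
  ord <- order(-score, seq_along(score))
  kept <- integer(0)
  for (f in ord)
    if (!length(kept) || all(abs(corMat[f, kept]) <= thr))
      kept <- c(kept, f)
  sort(kept)
}

# rank features by the L1-logistic regularization path: earlier entry =
# more important; ties broken by univariate separation, then index
l1EntryOrder <- function(x, y01, score) {
  p <- ncol(x)
  if (p < 2L) return(seq_len(p))
  fit <- tryCatch(
    suppressWarnings(glmnet::glmnet(x, y01, family = "binomial", alpha = 1,
                                    standardize = FALSE, nlambda = 60)),
    error = function(e) NULL)
  if (is.null(fit)) return(order(-score, seq_len(p)))
  B <- as.matrix(fit$beta)
  entry <- apply(B != 0, 1, function(r) if (any(r)) which(r)[1] else Inf)
  order(entry, -score, seq_len(p))
}

standardizeStats <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

applyStandardize <- function(x, st) sweep(sweep(x, 2, st$center), 2, st$scale, "/")

aucOf <- function(scores, y, positive) directionalAuc(scores, y, positive)$auc

## ---------------------------------------------------------------------------
## tuning
## ---------------------------------------------------------------------------

#' Tune a classifier on the source domain
#'
#' Runs the architecture's pipeline inside repeated stratified CV (default
#' 4 x 5). For ML, `nSamples` randomized hyperparameter draws (correlation
#' threshold, number of selected features k, ridge strength) are scored by
#' mean CV AUC and the winner is refit on the full source data. MEAN and
#' MSSK bypass feature selection entirely.
#'
#' @param spec A [ModelSpec-class].
#' @param data Source-domain data: a [RadiomicsFeatureSet-class] (reference
#'   scans) or `list(x = subjects x features matrix, y = labels)`.
#' @param domain Domain to use when `data` spans several.
#' @param positive Positive class label.
#' @return An object of class `xlungModel`: the frozen standardization,
#'   selected features, coefficients, winning hyperparameters, and
#'   `aucTuning` / `aucTuningSd` over the CV folds.
#' @export
tuneModel <- function(spec, data, domain = NULL, positive = "ild") {
  validObject(spec)
  xy <- asXY(data, domain, positive)
  x <- xy$x
  y <- xy$y
  if (length(unique(y)) < 2L) stop("source data must contain both classes")
  y01 <- as.integer(y == positive)
  folds <- makeFolds(y, spec@cvFolds, spec@cvRepeats, spec@seed)
  fixed <- fixedFeaturesFor(spec@architecture)
  if (!is.null(fixed)) {
    miss <- setdiff(fixed, colnames(x))
    if (length(miss)) stop("missing feature columns: ", paste(miss, collapse = ", "))
    cv <- vapply(folds, function(val) {
      tr <- setdiff(seq_len(nrow(x)), val)
      if (length(unique(y[val])) < 2L || length(unique(y[tr])) < 2L)
        return(NA_real_)
      st <- standardizeStats(x[tr, fixed, drop = FALSE])
      fit <- ridgeLogit(applyStandardize(x[tr, fixed, drop = FALSE], st),
                        y01[tr], lambda = 1e-6)
      sc <- drop(applyStandardize(x[val, fixed, drop = FALSE], st) %*% fit$beta)
      aucOf(sc, y[val], positive)
    }, numeric(1))
    st <- standardizeStats(x[, fixed, drop = FALSE])
    fit <- ridgeLogit(applyStandardize(x[, fixed, drop = FALSE], st), y01,
                      lambda = 1e-6)
    model <- list(architecture = spec@architecture, features = fixed,
                  center = st$center, scale = st$scale,
                  intercept = fit$intercept, beta = fit$beta, lambda = 1e-6,
                  hyper = NULL, aucTuning = mean(cv, na.rm = TRUE),
                  aucTuningSd = stats::sd(cv[!is.na(cv)]), cvAuc = cv,
                  positive = positive, spec = spec)
    class(model) <- "xlungModel"
    return(model)
  }
  ## ML architecture
  nS <- spec@nSamples
  samples <- withSeed(spec@seed + 1L, data.frame(
    thr = sample(spec@corThresholdGrid, nS, replace = TRUE),
    k = sample(seq(spec@kRange[1], spec@kRange[2]), nS, replace = TRUE),
    lambda = exp(stats::runif(nS, log(spec@lambdaRange[1]),
                              log(spec@lambdaRange[2])))))
  aucMat <- matrix(NA_real_, nS, length(folds))
  foldCenters <- vector("list", length(folds))
  for (fi in seq_along(folds)) {
    val <- folds[[fi]]
    tr <- setdiff(seq_len(nrow(x)), val)
    if (length(unique(y[val])) < 2L || length(unique(y[tr])) < 2L) next
    st <- standardizeStats(x[tr, , drop = FALSE])
    foldCenters[[fi]] <- st$center
    ztr <- applyStandardize(x[tr, , drop = FALSE], st)
    zval <- applyStandardize(x[val, , drop = FALSE], st)
    score <- vapply(seq_len(ncol(ztr)), function(j)
      abs(aucOf(ztr[, j], y[tr], positive) - 0.5), numeric(1))
    corMat <- suppressWarnings(stats::cor(ztr))
    corMat[!is.finite(corMat)] <- 0
    cache <- new.env(parent = emptyenv())
    prepFor <- function(thr) {
      key <- format(thr, digits = 10)
      if (!is.null(cache[[key]])) return(cache[[key]])
      kept <- pruneCorrelated(corMat, score, thr)
      ord <- l1EntryOrder(ztr[, kept, drop = FALSE], y01[tr], score[kept])
      res <- list(kept = kept, ranked = kept[ord])
      cache[[key]] <- res
      res
    }
    for (si in seq_len(nS)) {
      pr <- prepFor(samples$thr[si])
      feats <- utils::head(pr$ranked, min(samples$k[si], length(pr$ranked)))
      fit <- ridgeLogit(ztr[, feats, drop = FALSE], y01[tr], samples$lambda[si])
      sc <- drop(zval[, feats, drop = FALSE] %*% fit$beta)
      aucMat[si, fi] <- aucOf(sc, y[val], positive)
    }
  }
  cvAuc <- rowMeans(aucMat, na.rm = TRUE)
  best <- which.max(cvAuc)
  bestFoldAuc <- aucMat[best, ]
  ## refit on full source with the winning configuration
  st <- standardizeStats(x)
  z <- applyStandardize(x, st)
  score <- vapply(seq_len(ncol(z)), function(j)
    abs(aucOf(z[, j], y, positive) - 0.5), numeric(1))
  corMat <- suppressWarnings(stats::cor(z))
  corMat[!is.finite(corMat)] <- 0
  kept <- pruneCorrelated(corMat, score, samples$thr[best])
  ranked <- kept[l1EntryOrder(z[, kept, drop = FALSE], y01, score[kept])]
  feats <- colnames(x)[utils::head(ranked, min(samples$k[best], length(ranked)))]
  fit <- ridgeLogit(z[, feats, drop = FALSE], y01, samples$lambda[best])
  model <- list(architecture = "ML", features = feats,
                center = st$center[feats], scale = st$scale[feats],
                intercept = fit$intercept, beta = fit$beta,
                lambda = samples$lambda[best],
                hyper = list(corThreshold = samples$thr[best],
                             k = samples$k[best],
                             lambda = samples$lambda[best]),
                aucTuning = mean(bestFoldAuc, na.rm = TRUE),
                aucTuningSd = stats::sd(bestFoldAuc[!is.na(bestFoldAuc)]),
                cvAuc = bestFoldAuc, folds = folds,
                foldCenters = foldCenters, positive = positive, spec = spec)
  class(model) <- "xlungModel"
  model
}

#' @export
print.xlungModel <- function(x, ...) {
  cat("xlungModel [", x$architecture, "]: features ",
      paste(x$features, collapse = ", "), "\n", sep = "")
  cat(sprintf("  AUC tuning %.3f +/- %.3f\n", x$aucTuning, x$aucTuningSd))
  invisible(x)
}

#' Linear scores of a fitted model on new data
#'
#' Applies the frozen source standardization and coefficients; errors if
#' any required feature column is missing.
#'
#' @param model An `xlungModel`.
#' @param x Subjects x features matrix with named columns.
#' @return Numeric vector of probability scores.
#' @export
predictScores <- function(model, x) {
  x <- as.matrix(x)
  miss <- setdiff(model$features, colnames(x))
  if (length(miss)) stop("missing feature columns: ", paste(miss, collapse = ", "))
  z <- sweep(sweep(x[, model$features, drop = FALSE], 2, model$center), 2,
             model$scale, "/")
  stats::plogis(model$intercept + drop(z %*% model$beta))
}

## ---------------------------------------------------------------------------
## transfer, re-optimization, diagnostics
## ---------------------------------------------------------------------------

stratifiedBootIdx <- function(pos) {
  c(sample(which(pos), sum(pos), replace = TRUE),
    sample(which(!pos), sum(!pos), replace = TRUE))
}

#' Test a frozen model in the target domain
#'
#' The model (including its source-domain standardization) is applied
#' untouched to the target cohort; the directional AUC is reported with a
#' stratified bootstrap percentile confidence interval.
#'
#' @param model An `xlungModel` fitted by [tuneModel()].
#' @param data Target-domain data ([RadiomicsFeatureSet-class] or
#'   `list(x, y)`).
#' @param domain Domain selector when `data` spans several.
#' @param nBoot Bootstrap resamples (default 2000).
#' @param level Confidence level.
#' @param seed Integer seed for the bootstrap.
#' @return List with `auc`, `ci`, `nPos`, `nNeg`, and the `scores`.
#' @export
testTransfer <- function(model, data, domain = NULL, nBoot = 2000L,
                         level = 0.95, seed = 1L) {
  xy <- asXY(data, domain, model$positive)
  scores <- predictScores(model, xy$x)
  pos <- xy$y == model$positive
  if (!any(pos) || all(pos)) stop("target data must contain both classes")
  auc <- aucOf(scores, xy$y, model$positive)
  boot <- withSeed(seed, vapply(seq_len(nBoot), function(b) {
    idx <- stratifiedBootIdx(pos)
    aucOf(scores[idx], xy$y[idx], model$positive)
  }, numeric(1)))
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha), type = 1))
  list(auc = auc, ci = ci, nPos = sum(pos), nNeg = sum(!pos), scores = scores,
       labels = xy$y)
}

#' Re-optimize a transferred signature in the target domain
#'
#' Keeps the source-selected feature signature frozen and refits only the
#' classifier weights in the target domain under the same repeated CV,
#' measuring how predictive the signature itself is once the domain shift
#' is absorbed by refitting.
#'
#' @param model An `xlungModel` (its `features` are frozen).
#' @param data Target-domain data.
#' @param domain Domain selector.
#' @param cvRepeats,cvFolds CV layout (defaults mirror the tuning layout).
#' @param seed Integer seed.
#' @return List with `aucReopt`, `aucReoptSd`, per-fold `cvAuc` and the
#'   target-refit `model`.
#' @export
reoptimize <- function(model, data, domain = NULL,
                       cvRepeats = model$spec@cvRepeats,
                       cvFolds = model$spec@cvFolds, seed = 1L) {
  xy <- asXY(data, domain, model$positive)
  feats <- model$features
  miss <- setdiff(feats, colnames(xy$x))
  if (length(miss)) stop("missing feature columns: ", paste(miss, collapse = ", "))
  x <- xy$x[, feats, drop = FALSE]
  y <- xy$y
  y01 <- as.integer(y == model$positive)
  folds <- makeFolds(y, cvFolds, cvRepeats, seed)
  cv <- vapply(folds, function(val) {
    tr <- setdiff(seq_len(nrow(x)), val)
    if (length(unique(y[val])) < 2L || length(unique(y[tr])) < 2L)
      return(NA_real_)
    st <- standardizeStats(x[tr, , drop = FALSE])
    fit <- ridgeLogit(applyStandardize(x[tr, , drop = FALSE], st), y01[tr],
                      model$lambda)
    sc <- drop(applyStandardize(x[val, , drop = FALSE], st) %*% fit$beta)
    aucOf(sc, y[val], model$positive)
  }, numeric(1))
  st <- standardizeStats(x)
  fit <- ridgeLogit(applyStandardize(x, st), y01, model$lambda)
  refit <- model
  refit$center <- st$center
  refit$scale <- st$scale
  refit$intercept <- fit$intercept
  refit$beta <- fit$beta
  refit$aucTuning <- mean(cv, na.rm = TRUE)
  refit$aucTuningSd <- stats::sd(cv[!is.na(cv)])
  refit$cvAuc <- cv
  list(aucReopt = mean(cv, na.rm = TRUE),
       aucReoptSd = stats::sd(cv[!is.na(cv)]), cvAuc = cv, model = refit)
}

#' Diagnostics at the Youden-optimal cutoff
#'
#' Scans all observed score thresholds, picks the cutoff maximizing
#' Youden's J = TPR + TNR - 1 (ties resolved toward higher specificity),
#' and reports TPR, TNR, PPV, NPV, LR+ and LR- there, each with a
#' stratified bootstrap percentile CI (the cutoff is re-estimated within
#' every resample). An undefined LR+ (TNR = 1) is reported as `Inf`.
#'
#' @param scores Numeric classifier scores.
#' @param labels Class labels.
#' @param positive Positive class label.
#' @param nBoot Bootstrap resamples.
#' @param level Confidence level.
#' @param seed Integer seed.
#' @return List with `cutoff`, `J`, and a `metrics` data.frame
#'   (metric, value, lower, upper).
#' @export
thresholdDiagnostics <- function(scores, labels, positive = "ild",
                                 nBoot = 2000L, level = 0.95, seed = 1L) {
  pos <- labels == positive
  if (!any(pos) || all(pos)) stop("both classes must be present")
  oneScan <- function(scores, pos) {
    cand <- sort(unique(scores))
    tpr <- vapply(cand, function(cc) mean(scores[pos] >= cc), numeric(1))
    tnr <- vapply(cand, function(cc) mean(scores[!pos] < cc), numeric(1))
    J <- tpr + tnr - 1
    best <- which(J >= max(J) - 1e-12)
    best <- best[order(-tnr[best], -cand[best])][1]   # ties -> higher specificity
    cc <- cand[best]
    tp <- sum(scores[pos] >= cc); fn <- sum(pos) - tp
    fp <- sum(scores[!pos] >= cc); tn <- sum(!pos) - fp
    c(cutoff = cc, J = J[best],
      TPR = tp / (tp + fn), TNR = tn / (tn + fp),
      PPV = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      NPV = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
      LRpos = if (fp > 0) (tp / (tp + fn)) / (fp / (fp + tn)) else Inf,
      LRneg = if (tn > 0) (fn / (tp + fn)) / (tn / (fp + tn)) else Inf)
  }
  obs <- oneScan(scores, pos)
  boot <- withSeed(seed, vapply(seq_len(nBoot), function(b) {
    idx <- stratifiedBootIdx(pos)
    oneScan(scores[idx], pos[idx])
  }, numeric(8)))
  alpha <- (1 - level) / 2
  metrics <- c("TPR", "TNR", "PPV", "NPV", "LRpos", "LRneg")
  tab <- data.frame(
    metric = metrics,
    value = unname(obs[metrics]),
    lower = vapply(metrics, function(m)
      unname(stats::quantile(boot[m, ], alpha, type = 1, na.rm = TRUE)),
      numeric(1)),
    upper = vapply(metrics, function(m)
      unname(stats::quantile(boot[m, ], 1 - alpha, type = 1, na.rm = TRUE)),
      numeric(1)),
    row.names = NULL)
  list(cutoff = unname(obs["cutoff"]), J = unname(obs["J"]), metrics = tab)
}

#' Coefficient directions of a linear model
#'
#' Signs of the standardized coefficients — e.g. for the MSSK architecture
#' a (+, +, -, -) pattern over (mean, SD, skewness, kurtosis) means higher
#' mean/SD and lower skewness/kurtosis increase the modeled ILD risk.
#'
#' @param model An `xlungModel` with a linear final classifier.
#' @return data.frame with feature, coefficient, sign; carries an
#'   `applicable` attribute (FALSE for non-linear classifiers).
#' @export
signReport <- function(model) {
  stopifnot(inherits(model, "xlungModel"))
  out <- data.frame(feature = model$features,
                    coefficient = unname(model$beta),
                    sign = ifelse(model$beta > 0, "+",
                                  ifelse(model$beta < 0, "-", "0")),
                    stringsAsFactors = FALSE)
  attr(out, "applicable") <- TRUE
  out
}
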