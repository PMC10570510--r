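# Diagnostic modelling: chi-square feature ranking, SMOTE class balancing,
# a boosted classification-tree ensemble, SMOTE-nested leave-one-out
# cross-validation, the clinical-blood benchmark, and the composite and
# cascading models.  Pneumonia is coded 0, pneumonitis (the positive class) 1.

#' Univariate chi-square feature ranking
#'
#' Each continuous feature is quantile-binned (default 4 bins; features with
#' at most two distinct values are used as-is) into a contingency table
#' against the class label, tested with Pearson's chi-square (no continuity
#' correction), and scored as `-log(p)` (natural log), so higher scores mean
#' greater importance.  Constant features get p = 1, score 0.  Ties in score
#' are broken lexicographically by feature name.
#'
#' @param X data.frame or matrix of features (rows = patients).
#' @param y 0/1 class labels.
#' @param bins quantile bin count for continuous features.
#' @return data.frame (feature, p, score), sorted by descending score.
#' @export
chi2Rank <- function(X, y, bins = 4L) {
  X <- as.data.frame(X)
  if (length(unique(y)) < 2 || min(table(y)) < 2)
    stop("need at least 2 patients per class")
  scoreOne <- function(x) {
    ux <- unique(x)
    if (length(ux) < 2) return(1)
    if (length(ux) > 2) {
      br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                                   type = 7))
      if (length(br) < 3) return(1) # collapses to one bin
      x <- cut(x, breaks = br, include.lowest = TRUE)
    }
    tab <- table(x, y)
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    if (nrow(tab) < 2) return(1)
    p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    if (!is.finite(p)) 1 else max(p, .Machine$double.xmin)
  }
  p <- vapply(X, scoreOne, 0)
  out <- data.frame(feature = colnames(X), p = p, score = -log(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$score, out$feature), , drop = FALSE]
}

#' SMOTE minority oversampling
#'
#' Upsamples the minority class to the majority count.  Each synthetic
#' sample lies on the segment between a minority sample and one of its
#' `k` nearest minority neighbours (Euclidean); originals are preserved.
#' `k` is reduced automatically when the minority class is small; fewer than
#' two minority samples is an error.
#'
#' @param X numeric matrix / data.frame of training features.
#' @param y 0/1 labels.
#' @param k neighbour count (classical default 5).
#' @param seed RNG seed.
#' @return list with balanced `X` (matrix) and `y`.
#' @export
smoteOversample <- function(X, y, k = 5L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  tab <- table(factor(y, levels = c(0L, 1L)))
  if (tab[1] == tab[2]) return(list(X = X, y = y))
  minLab <- as.integer(names(tab)[which.min(tab)])
  nMin <- min(tab); nMaj <- max(tab)
  if (nMin < 2) stop("minority class needs at least 2 samples for SMOTE")
  k <- min(k, nMin - 1L)
  Xmin <- X[y == minLab, , drop = FALSE]
  dd <- as.matrix(stats::dist(Xmin))
  diag(dd) <- Inf
  nnRaw <- apply(dd, 1, function(r) order(r)[seq_len(k)])
  nn <- if (k == 1L) matrix(nnRaw, ncol = 1L) else t(nnRaw)
  nSyn <- nMaj - nMin
  base <- rep(seq_len(nMin), length.out = nSyn)
  syn <- withSeed(seed, {
    nbPick <- sample.int(k, nSyn, replace = TRUE)
    tt <- stats::runif(nSyn)
    Xmin[base, , drop = FALSE] +
      tt * (Xmin[nn[cbind(base, nbPick)], , drop = FALSE] -
              Xmin[base, , drop = FALSE])
  })
  list(X = rbind(X, syn), y = c(y, rep(minLab, nSyn)))
}

#' Boosted classification-tree ensemble specification
#'
#' The ensemble is discrete adaptive boosting of shallow classification
#' trees: 100 boosting rounds of depth-2 rpart trees with learning rate 0.5.
#'
#' @param nTrees boosting rounds.
#' @param maxDepth tree depth.
#' @param learnRate shrinkage on the tree weights.
#' @return list of class `ClassifierSpec`.
#' @export
boostSpec <- function(nTrees = 100L, maxDepth = 2L, learnRate = 0.5) {
  structure(list(nTrees = as.integer(nTrees), maxDepth = as.integer(maxDepth),
                 learnRate = learnRate), class = "ClassifierSpec")
}

#' Fit a boosted classification-tree ensemble
#'
#' Discrete AdaBoost over depth-limited rpart classification trees.  Sample
#' weights start uniform; each round fits a tree to the weighted sample,
#' computes the weighted error e, sets the tree weight
#' `alpha = learnRate * 0.5 * log((1-e)/e)` and reweights misclassified
#' samples by `exp(alpha)` (correct ones by `exp(-alpha)`).  Boosting stops
#' early when a round separates the weighted sample perfectly or fails to
#' beat chance.  Prediction is the sign of the alpha-weighted vote; a zero
#' vote predicts the lower label (0).
#'
#' @param X feature matrix / data.frame.
#' @param y 0/1 labels.
#' @param spec a [boostSpec()].
#' @return object of class `boostedTrees` with a `predict` method.
#' @export
fitBoostedTrees <- function(X, y, spec = boostSpec()) {
  X <- as.data.frame(X)
  colnames(X) <- make.names(colnames(X))
  y <- as.integer(y)
  n <- nrow(X)
  w <- rep(1 / n, n)
  trees <- list(); alphas <- numeric(0)
  yf <- factor(y, levels = c(0L, 1L))
  ctl <- rpart::rpart.control(maxdepth = spec$maxDepth, cp = 0, minsplit = 4,
                              minbucket = 2, xval = 0, maxsurrogate = 0,
                              maxcompete = 0)
  dat <- cbind(X, .y = yf)
  for (m in seq_len(spec$nTrees)) {
    fit <- rpart::rpart(.y ~ ., data = dat, weights = w, method = "class",
                        control = ctl)
    pred <- as.integer(as.character(predict(fit, X, type = "class")))
    mis <- pred != y
    e <- sum(w[mis])
    if (e >= 0.5) break # no better than chance on the weighted sample
    eClamped <- max(e, 1e-10)
    alpha <- spec$learnRate * 0.5 * log((1 - eClamped) / eClamped)
    trees[[length(trees) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    if (e <= 0) break # perfect separation
    w <- w * exp(ifelse(mis, alpha, -alpha))
    w <- w / sum(w)
  }
  structure(list(trees = trees, alphas = alphas, spec = spec,
                 features = colnames(X)),
            class = "boostedTrees")
}

#' @export
predict.boostedTrees <- function(object, newdata, type = c("class", "score"),
                                 ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)
  colnames(newdata) <- make.names(colnames(newdata))
  if (length(object$trees) == 0)
    return(if (type == "class") rep(0L, nrow(newdata)) else rep(0, nrow(newdata)))
  votes <- vapply(seq_along(object$trees), function(m) {
    pred <- as.integer(as.character(
      predict(object$trees[[m]], newdata, type = "class")))
    object$alphas[m] * (2 * pred - 1)
  }, numeric(nrow(newdata)))
  score <- if (is.matrix(votes)) rowSums(votes) else sum(votes)
  if (type == "score") score else as.integer(score > 0)
}

#' SMOTE-nested leave-one-out cross-validation
#'
#' Exactly n folds for n patients.  Within each fold, strictly on the
#' training rows: features are ranked by [chi2Rank()], the top
#' `nTop` kept, the training rows SMOTE-balanced, the boosted ensemble
#' fitted, and the single held-out patient predicted.  The held-out row
#' never enters ranking, SMOTE or fitting, which is the leakage-safe
#' nesting.
#'
#' @param X feature matrix / data.frame (rows = patients).
#' @param y 0/1 labels (pneumonitis = 1 = positive).
#' @param nTop number of top-ranked features per fold.
#' @param spec a [boostSpec()].
#' @param seed RNG seed (per-fold SMOTE seeds are derived from it).
#' @param smoteK SMOTE neighbour count.
#' @return list of class `loocvReport`: `confusion` (named TP/FP/TN/FN),
#'   `metrics` (accuracy, sensitivity, specificity), `predictions`
#'   data.frame, `nTop`, `n`.
#' @export
loocvEvaluate <- function(X, y, nTop = 10L, spec = boostSpec(), seed = 1L,
                          smoteK = 5L) {
  X <- as.data.frame(X)
  y <- as.integer(y)
  n <- nrow(X)
  if (n < 10) warning("fewer than 10 patients; LOOCV estimates will be unstable")
  if (length(unique(y)) < 2) stop("both classes must be present")
  pred <- integer(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- y[-i]
    rank <- chi2Rank(Xtr, ytr)
    top <- rank$feature[seq_len(min(nTop, nrow(rank)))]
    bal <- smoteOversample(Xtr[, top, drop = FALSE], ytr,
                           k = smoteK, seed = seed + i)
    fit <- fitBoostedTrees(bal$X, bal$y, spec)
    pred[i] <- predict(fit, X[i, top, drop = FALSE])
  }
  cm <- confusionFromPredictions(y, pred)
  structure(list(confusion = cm, metrics = confusionMetrics(cm),
                 predictions = data.frame(patient = seq_len(n), truth = y,
                                          predicted = pred),
                 nTop = nTop, n = n),
            class = "loocvReport")
}

#' @export
print.loocvReport <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "LOOCV (n = %d, top %d features): accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
    x$n, x$nTop, 100 * m["accuracy"], 100 * m["sensitivity"],
    100 * m["specificity"]))
  invisible(x)
}

#' Iterative top-k feature-count selection
#'
#' Runs [loocvEvaluate()] for every candidate feature count in `kGrid` and
#' returns the count maximizing LOOCV accuracy (ties go to the smaller k),
#' together with the full grid report.
#'
#' @param X,y,spec,seed as in [loocvEvaluate()].
#' @param kGrid candidate top-feature counts.
#' @return list: `bestK`, `report` (data.frame k/accuracy/sensitivity/
#'   specificity), `bestRun` (the winning `loocvReport`).
#' @export
selectTopK <- function(X, y, kGrid = c(1, 2, 5, 10, 20), spec = boostSpec(),
                       seed = 1L) {
  kGrid <- sort(unique(as.integer(kGrid)))
  if (!length(kGrid)) stop("empty feature-count grid")
  if (any(kGrid < 1) || any(kGrid > ncol(X)))
    stop("kGrid must lie within [1, n_features]")
  runs <- lapply(kGrid, function(k) loocvEvaluate(X, y, nTop = k,
                                                  spec = spec, seed = seed))
  report <- data.frame(
    k = kGrid,
    accuracy = vapply(runs, function(r) r$metrics["accuracy"], 0),
    sensitivity = vapply(runs, function(r) r$metrics["sensitivity"], 0),
    specificity = vapply(runs, function(r) r$metrics["specificity"], 0))
  best <- which.max(report$accuracy) # which.max takes the first (smallest k)
  list(bestK = kGrid[best], report = report, bestRun = runs[[best]])
}

#' Prepare the clinical-blood benchmark feature matrix
#'
#' Eight clinical columns (three symptoms at two timepoints, age, sex) and
#' nine blood columns, with WBC and platelets replaced by their natural
#' logs at both timepoints.  Non-positive counts are floored at a small
#' constant (1e-3) before the log, with a warning.
#'
#' @param records data.frame from [generateClinicalTable()] (or with the
#'   same columns).
#' @return numeric matrix with 17 documented columns.
#' @export
prepareBenchmarkFeatures <- function(records) {
  needed <- c("cough_baseline", "fever_baseline", "dyspnea_baseline",
              "cough_syndrome", "fever_syndrome", "dyspnea_syndrome",
              "age", "sex",
              "wbc_baseline", "wbc_syndrome", "anc_baseline", "anc_syndrome",
              "alc_baseline", "alc_syndrome",
              "platelets_baseline", "platelets_syndrome", "blasts_baseline")
  miss <- setdiff(needed, colnames(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  counts <- c("wbc_baseline", "wbc_syndrome", "anc_baseline", "anc_syndrome",
              "alc_baseline", "alc_syndrome", "platelets_baseline",
              "platelets_syndrome", "blasts_baseline")
  if (nrow(records) && any(records[counts] < 0))
    stop("negative counts rejected")
  safeLog <- function(v) {
    if (any(v <= 0)) {
      warning("non-positive counts floored at 1e-3 before log transform")
      v <- pmax(v, 1e-3)
    }
    log(v)
  }
  out <- cbind(
    as.matrix(records[, c("cough_baseline", "fever_baseline",
                          "dyspnea_baseline", "cough_syndrome",
                          "fever_syndrome", "dyspnea_syndrome",
                          "age", "sex")]),
    log_wbc_baseline = safeLog(records$wbc_baseline),
    log_wbc_syndrome = safeLog(records$wbc_syndrome),
    anc_baseline = records$anc_baseline,
    anc_syndrome = records$anc_syndrome,
    alc_baseline = records$alc_baseline,
    alc_syndrome = records$alc_syndrome,
    log_platelets_baseline = safeLog(records$platelets_baseline),
    log_platelets_syndrome = safeLog(records$platelets_syndrome),
    blasts_baseline = records$blasts_baseline)
  out
}

#' Cascading agreement rule
#'
#' A diagnosis is made only when the clinical-blood benchmark and the
#' habitat model agree; disagreements are labelled ambiguous.
#'
#' @param predBenchmark,predHabitat 0/1 prediction vectors.
#' @return character vector in `{"pneumonia", "pneumonitis", "ambiguous"}`.
#' @export
cascadePredict <- function(predBenchmark, predHabitat) {
  if (length(predBenchmark) != length(predHabitat))
    stop("prediction vectors differ in length")
  out <- ifelse(predBenchmark == predHabitat,
                ifelse(predBenchmark == 1, "pneumonitis", "pneumonia"),
                "ambiguous")
  as.character(out)
}

#' Composite imaging-blood model
#'
#' Column-concatenates the MSI and benchmark feature banks for the same
#' patients, selects the feature count on the combined matrix with
#' [selectTopK()], and reports the winning SMOTE-nested LOOCV run together
#' with a pooled feature-importance ranking (computed on the full data for
#' reporting only; in-fold ranking governs every prediction).
#'
#' @param Xmsi,Xbenchmark aligned feature matrices (same patient rows).
#' @param y 0/1 labels.
#' @param kGrid,spec,seed passed to [selectTopK()].
#' @return list: `bestK`, `report`, `bestRun`, `importance`, `nFeatures`.
#' @export
fitComposite <- function(Xmsi, Xbenchmark, y, kGrid = c(1, 2, 5, 10, 20),
                         spec = boostSpec(), seed = 1L) {
  if (nrow(Xmsi) != nrow(Xbenchmark) || nrow(Xmsi) != length(y))
    stop("patient rows are misaligned")
  X <- cbind(as.matrix(Xmsi), as.matrix(Xbenchmark))
  sel <- selectTopK(X, y, kGrid = kGrid, spec = spec, seed = seed)
  c(sel, list(importance = chi2Rank(X, y), nFeatures = ncol(X)))
}
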