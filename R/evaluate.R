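# Evaluation protocol: confusion-matrix metrics, ROC/AUC by threshold sweep,
# stratified 70/30 hold-out splitting, and the repeated-experiment driver
# comparing PCA-SVM against PPCA-SVM.

#' Confusion counts from true and predicted labels
#'
#' @param truth true binary labels (0/1).
#' @param pred predicted binary labels (0/1).
#' @return a list with integer \code{TP}, \code{TN}, \code{FP}, \code{FN}.
#' @export
confusionCounts <- function(truth, pred) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  stopifnot(length(truth) == length(pred),
            all(truth %in% 0:1), all(pred %in% 0:1))
  list(TP = sum(truth == 1L & pred == 1L),
       TN = sum(truth == 0L & pred == 0L),
       FP = sum(truth == 0L & pred == 1L),
       FN = sum(truth == 1L & pred == 0L))
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' Accuracy = (TP+TN)/(TP+TN+FP+FN) x 100, sensitivity = TP/(FN+TP) x 100,
#' specificity = TN/(FP+TN) x 100. A metric whose denominator is zero is
#' reported as \code{NA} (undefined), never as 0 or 100.
#'
#' @param counts a list with \code{TP}, \code{TN}, \code{FP}, \code{FN}
#'   (as from \code{\link{confusionCounts}}).
#' @return a list with \code{accuracy}, \code{sensitivity},
#'   \code{specificity}, all in percent.
#' @examples
#' classificationMetrics(list(TP = 3, TN = 2, FP = 1, FN = 4))
#' @export
classificationMetrics <- function(counts) {
  with(counts, {
    total <- TP + TN + FP + FN
    if (total == 0) stop("no evaluated samples")
    list(
      accuracy = 100 * (TP + TN) / total,
      sensitivity = if (FN + TP > 0) 100 * TP / (FN + TP) else NA_real_,
      specificity = if (FP + TN > 0) 100 * TN / (FP + TN) else NA_real_)
  })
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique score values (ties grouped),
#' yielding a curve from (0,0) to (1,1) sorted by false-positive rate, and
#' integrates it with the trapezoidal rule. Invariant under strictly
#' increasing transformations of the scores.
#'
#' @param y binary labels (0/1), both classes present.
#' @param scores finite decision values; larger means more positive.
#' @return a list with \code{points} (data.frame \code{fpr}, \code{tpr}) and
#'   scalar \code{auc}.
#' @export
rocCurve <- function(y, scores) {
  y <- .checkBinaryLabels(y)
  scores <- as.numeric(scores)
  stopifnot(length(y) == length(scores), all(is.finite(scores)))
  nPos <- sum(y == 1L); nNeg <- sum(y == 0L)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  grp <- cumsum(!duplicated(ss))           # tie groups of equal scores
  tpCum <- cumsum(ys == 1L)
  fpCum <- cumsum(ys == 0L)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tpr <- c(0, tpCum[last] / nPos)
  fpr <- c(0, fpCum[last] / nNeg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Stratified random train/test split
#'
#' Draws a stratified random split: within each class,
#' \code{round(fraction * n_class)} samples go to the training set (R's
#' round-half-even), the remainder to the test set. Deterministic under
#' \code{seed}; train and test indices are disjoint and exhaustive.
#'
#' @param labels binary labels (0/1), each class with >= 2 members.
#' @param fraction training fraction (default 0.7).
#' @param seed RNG seed.
#' @return a list with integer vectors \code{train} and \code{test}.
#' @export
stratifiedSplit <- function(labels, fraction = 0.7, seed = 1L) {
  y <- .checkBinaryLabels(labels)
  stopifnot(fraction > 0, fraction < 1, length(y) >= 10L)
  if (any(table(y) < 2L)) stop("each class needs at least 2 members")
  train <- integer(0)
  .withSeed(seed, {
    for (cl in c(1L, 0L)) {
      idx <- which(y == cl)
      nTrain <- round(fraction * length(idx))
      train <- c(train, idx[sample.int(length(idx), nTrain)])
    }
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(y), train))
}

#' Average metric rows across runs
#'
#' Arithmetic mean of each metric per method, computed on the unrounded
#' per-run values; a \code{display} copy rounded to 2 decimals is attached
#' for table-shaped reporting.
#'
#' @param runs a data.frame with columns \code{method}, \code{accuracy},
#'   \code{sensitivity}, \code{specificity} (and optionally \code{auc}),
#'   one row per run.
#' @return a data.frame with one row per method and the metric means, with
#'   attribute \code{"display"} holding the 2-decimal rounded copy.
#' @export
averageMetrics <- function(runs) {
  stopifnot(is.data.frame(runs), nrow(runs) >= 1L)
  cols <- intersect(c("accuracy", "sensitivity", "specificity", "auc"),
                    names(runs))
  out <- do.call(rbind, lapply(split(runs, runs$method), function(g) {
    cbind(data.frame(method = g$method[1L], stringsAsFactors = FALSE),
          as.data.frame(lapply(g[cols], mean)))
  }))
  rownames(out) <- NULL
  disp <- out
  disp[cols] <- lapply(disp[cols], round, digits = 2L)
  attr(out, "display") <- disp
  out
}

# One hold-out run of one method. `Xfit` is the data the reducer is fitted
# on (the training partition, or the pooled set under pooledReduction);
# scores are always computed for the training and test partitions.
.oneRun <- function(Xfit, Xtr, ytr, Xte, yte, method, q, scoreMode, svmCfg,
                    ppcaSeed, ppcaTol, ppcaMaxIter, pcaFit = NULL) {
  if (method == "pca-svm") {
    red <- if (is.null(pcaFit)) fitPCA(Xfit, q) else pcaFit
    Ztr <- scoresMatrix(latentScores(red, Xtr))
    Zte <- scoresMatrix(latentScores(red, Xte))
  } else {
    red <- fitPPCA(Xfit, q, method = "em", tol = ppcaTol,
                   maxIter = ppcaMaxIter, seed = ppcaSeed)
    Ztr <- scoresMatrix(latentScores(red, Xtr, mode = scoreMode))
    Zte <- scoresMatrix(latentScores(red, Xte, mode = scoreMode))
  }
  clf <- trainWithGridSearch(Ztr, ytr, svmCfg)
  pr <- predict(clf, Zte)
  counts <- confusionCounts(yte, pr$labels)
  met <- classificationMetrics(counts)
  roc <- rocCurve(yte, pr$decision)
  list(counts = counts, metrics = met, roc = roc, q = q,
       bestC = clf@bestC, bestG = clf@bestG)
}

#' Repeated stratified hold-out comparison of PCA-SVM and PPCA-SVM
#'
#' For each repeat r = 1..nRepeats: draw a stratified 70/30 split (seeded
#' with \code{seed + r}); fit the dimension reducer on the training partition
#' only (or on the pooled data when \code{pooledReduction = TRUE}); when
#' \code{q = "auto"} choose the latent dimension as the smallest q reaching
#' \code{cumvar} cumulative explained variance of the training eigenvalue
#' spectrum; run the cross-validated (c, g) grid search on the training
#' scores (fold seed \code{seed + 20000 + r}); train the SVM and predict the
#' held-out partition; record confusion counts, accuracy / sensitivity /
#' specificity, ROC points and AUC. PPCA EM initialization uses seed
#' \code{seed + 10000 + r}. Finally per-method averages are computed on the
#' unrounded values.
#'
#' @param set a labeled \linkS4class{SpectrumSet} (or N-by-d matrix with
#'   \code{labels}).
#' @param methods subset of \code{c("pca-svm", "ppca-svm")}.
#' @param nRepeats number of independent hold-out repetitions.
#' @param q \code{"auto"} (cumulative-variance rule) or a fixed integer.
#' @param cumvar cumulative-variance threshold used when \code{q = "auto"}.
#' @param svmCfg an \code{\link{svmConfig}} (its seed is overridden per run).
#' @param seed master seed; per-run seeds are derived by fixed offsets.
#' @param scoreMode PPCA projection mode (see \code{\link{latentScores}}).
#'   The experiment default is \code{"cross-projection"}: under the
#'   cumulative-variance policy the latent dimension approaches the training
#'   rank, the residual variance estimate approaches zero, and the
#'   posterior-mean projection then whitens near-null directions whose
#'   out-of-sample variance it grossly amplifies, starving the RBF kernel;
#'   the cross-projection keeps the eigenvalue scaling and has no such
#'   failure mode.
#' @param pooledReduction fit the reducer on all samples before splitting
#'   (information leaks into the test partition; off by default, available
#'   to mirror protocols that fitted the reducer on the pooled data).
#' @param ppcaTol,ppcaMaxIter EM convergence settings used inside runs.
#' @param trainFraction training fraction of the split.
#' @param labels label vector, only needed when \code{set} is a bare matrix.
#' @param verbose print one line per completed run.
#' @return a list of class \code{"msExperimentReport"}: \code{runs} (per-run
#'   metric data.frame), \code{roc} (list of per-run ROC point data.frames),
#'   \code{averages} (per-method means), \code{config} (settings snapshot)
#'   and \code{seeds}.
#' @export
runExperiment <- function(set, methods = c("pca-svm", "ppca-svm"),
                          nRepeats = 10L, q = "auto", cumvar = 0.9999,
                          svmCfg = svmConfig(), seed = 1L,
                          scoreMode = "cross-projection",
                          pooledReduction = FALSE,
                          ppcaTol = 1e-6, ppcaMaxIter = 200L,
                          trainFraction = 0.7, labels = NULL,
                          verbose = FALSE) {
  methods <- match.arg(methods, c("pca-svm", "ppca-svm"),
                       several.ok = TRUE)
  if (is(set, "SpectrumSet")) {
    X <- intensityMatrix(set)
    y <- classLabels(set)
  } else {
    X <- as.matrix(set)
    y <- labels
  }
  if (is.null(y) || anyNA(y))
    stop("a fully labeled data set is required")
  y <- .checkBinaryLabels(y)
  seed <- as.integer(seed)
  runRows <- list()
  rocList <- list()
  for (r in seq_len(nRepeats)) {
    sp <- stratifiedSplit(y, fraction = trainFraction, seed = seed + r)
    Xtr <- X[sp$train, , drop = FALSE]; ytr <- y[sp$train]
    Xte <- X[sp$test, , drop = FALSE]; yte <- y[sp$test]
    fitX <- if (pooledReduction) X else Xtr
    qCap <- min(nrow(fitX) - 1L, ncol(fitX) - 1L)
    qFixed <- if (identical(q, "auto")) NULL else min(as.integer(q), qCap)
    # PCA fit doubles as the eigenvalue spectrum for auto-q
    pcaProbe <- fitPCA(fitX, if (is.null(qFixed)) qCap else qFixed)
    qUse <- if (is.null(qFixed))
      min(chooseLatentDim(pcaProbe@allEigenvalues, cumvar), qCap)
    else qFixed
    pcaFit <- if (qUse == ncol(pcaProbe@components)) pcaProbe
      else fitPCA(fitX, qUse)
    cfgRun <- svmCfg
    cfgRun$seed <- seed + 20000L + r
    for (m in methods) {
      res <- .oneRun(fitX, Xtr, ytr, Xte, yte, m, qUse, scoreMode, cfgRun,
                     ppcaSeed = seed + 10000L + r,
                     ppcaTol = ppcaTol, ppcaMaxIter = ppcaMaxIter,
                     pcaFit = if (m == "pca-svm") pcaFit else NULL)
      runRows[[length(runRows) + 1L]] <- data.frame(
        run = r, method = m,
        TP = res$counts$TP, TN = res$counts$TN,
        FP = res$counts$FP, FN = res$counts$FN,
        accuracy = res$metrics$accuracy,
        sensitivity = res$metrics$sensitivity,
        specificity = res$metrics$specificity,
        auc = res$roc$auc, q = res$q,
        bestC = res$bestC, bestG = res$bestG,
        stringsAsFactors = FALSE)
      rocList[[paste0(m, "_run", r)]] <- res$roc$points
      if (verbose)
        message(sprintf("run %d %-8s acc %.2f sens %.2f spec %.2f auc %.3f",
                        r, m, res$metrics$accuracy, res$metrics$sensitivity,
                        res$metrics$specificity, res$roc$auc))
    }
  }
  runs <- do.call(rbind, runRows)
  report <- list(
    runs = runs,
    roc = rocList,
    averages = averageMetrics(runs),
    config = list(methods = methods, nRepeats = nRepeats, q = q,
                  cumvar = cumvar, scoreMode = scoreMode,
                  pooledReduction = pooledReduction,
                  trainFraction = trainFraction,
                  ppcaTol = ppcaTol, ppcaMaxIter = ppcaMaxIter,
                  svm = unclass(svmCfg)),
    seeds = list(master = seed, split = "seed + r",
                 ppcaInit = "seed + 10000 + r",
                 cvFolds = "seed + 20000 + r"))
  class(report) <- "msExperimentReport"
  report
}

#' @export
print.msExperimentReport <- function(x, ...) {
  cat("Repeated hold-out experiment:", x$config$nRepeats, "repeats,",
      "methods:", paste(x$config$methods, collapse = ", "), "\n")
  cat("Per-method averages (percent):\n")
  print(attr(x$averages, "display"), row.names = FALSE)
  invisible(x)
}

#' Serialize an experiment report to JSON
#'
#' Writes the full report (per-run rows, ROC points, averages, configuration
#' and seeds) as JSON with full numeric precision. The same data, settings
#' and seed produce a byte-identical file.
#'
#' @param report an \code{"msExperimentReport"} from
#'   \code{\link{runExperiment}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeExperimentReport <- function(report, path) {
  out <- unclass(report)
  out$averages <- {
    av <- out$averages
    attr(av, "display") <- NULL
    av
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
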