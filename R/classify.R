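# RBF-SVM classification of latent scores: stratified k-fold cross-validated
# grid search over the soft-margin penalty c and kernel width g, training
# behind a per-feature standardizer learned on the training scores only.
# The SVM solver itself is e1071 (libsvm); it is configured, never re-derived.

#' SVM hyperparameter search configuration
#'
#' The conventional exponential grids of the libsvm practitioner guide:
#' \code{c} over \eqn{2^{-5}, 2^{-3}, \ldots, 2^{15}} and \code{g} over
#' \eqn{2^{-15}, 2^{-13}, \ldots, 2^{3}}, searched by stratified k-fold
#' cross-validation (default 10-fold).
#'
#' @param cGrid positive penalty values to search.
#' @param gGrid positive RBF width values to search.
#' @param kFolds number of cross-validation folds (>= 2).
#' @param seed fold-assignment seed.
#' @return a list of class \code{"msSVMConfig"}.
#' @export
svmConfig <- function(cGrid = 2^seq(-5, 15, by = 2),
                      gGrid = 2^seq(-15, 3, by = 2),
                      kFolds = 10L, seed = 1L) {
  stopifnot(all(cGrid > 0), all(gGrid > 0), kFolds >= 2L)
  cfg <- list(cGrid = sort(as.numeric(cGrid)),
              gGrid = sort(as.numeric(gGrid)),
              kFolds = as.integer(kFolds), seed = as.integer(seed))
  class(cfg) <- "msSVMConfig"
  cfg
}

.checkBinaryLabels <- function(y) {
  y <- as.integer(y)
  if (anyNA(y) || !all(y %in% c(0L, 1L)))
    stop("labels must be binary 0/1 with no NA")
  if (length(unique(y)) < 2L)
    stop("both classes must be present")
  y
}

# Stratified fold assignment: within each class, samples are shuffled
# (seeded) and dealt round-robin into k folds.
.stratifiedFolds <- function(y, k, seed) {
  fold <- integer(length(y))
  .withSeed(seed, {
    for (cl in sort(unique(y))) {
      idx <- which(y == cl)
      if (length(idx) < k)
        stop("kFolds = ", k, " exceeds the count of class ", cl,
             " (", length(idx), ")")
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep(seq_len(k), length.out = length(idx))
    }
  })
  fold
}

.fitScaler <- function(Z) {
  ctr <- colMeans(Z)
  scl <- apply(Z, 2L, stats::sd)
  zero <- !is.finite(scl) | scl == 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance feature(s); sd treated as 1")
    scl[zero] <- 1
  }
  list(center = ctr, scale = scl)
}

.applyScaler <- function(Z, scaler) {
  sweep(sweep(Z, 2L, scaler$center, "-"), 2L, scaler$scale, "/")
}

.fitSVM <- function(Z, y, c, g) {
  e1071::svm(x = Z, y = factor(y, levels = c("0", "1")),
             kernel = "radial", cost = c, gamma = g, scale = FALSE)
}

# Predict labels and ROC-ready signed decision values (positive value <=>
# predicted cancer). libsvm's decision-value sign refers to the first class
# of the comparison named in the column header, so orientation is fixed from
# that header.
.predictSVM <- function(fit, Z) {
  pr <- stats::predict(fit, Z, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  lab <- as.integer(as.character(pr))
  first <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]][1L]
  dv <- as.numeric(dv[, 1L])
  if (first == "0") dv <- -dv
  list(labels = lab, decision = dv)
}

#' Cross-validated grid search for (c, g)
#'
#' Computes the mean stratified k-fold cross-validation accuracy for every
#' pair in the configured grids and returns the best pair; ties are broken
#' toward the smaller \code{c}, then the smaller \code{g}. The feature
#' standardizer is refitted inside each training fold, so no information
#' leaks from held-out folds.
#'
#' @param Z N-by-q numeric matrix of latent scores (or
#'   \linkS4class{LatentScores}).
#' @param y binary labels (0/1), both classes present.
#' @param cfg an \code{\link{svmConfig}}.
#' @return a list with \code{bestC}, \code{bestG}, \code{bestAccuracy}
#'   (percent) and \code{cvTable} (a data.frame with one row per grid cell).
#' @export
svmGridSearch <- function(Z, y, cfg = svmConfig()) {
  if (is(Z, "LatentScores")) Z <- Z@Z
  Z <- as.matrix(Z)
  y <- .checkBinaryLabels(y)
  stopifnot(nrow(Z) == length(y))
  if (nrow(Z) < cfg$kFolds) stop("fewer samples than folds")
  fold <- .stratifiedFolds(y, cfg$kFolds, cfg$seed)
  cells <- expand.grid(c = cfg$cGrid, g = cfg$gGrid,
                       KEEP.OUT.ATTRS = FALSE)
  acc <- numeric(nrow(cells))
  for (f in seq_len(cfg$kFolds)) {
    tr <- fold != f
    scaler <- .fitScaler(Z[tr, , drop = FALSE])
    Ztr <- .applyScaler(Z[tr, , drop = FALSE], scaler)
    Zte <- .applyScaler(Z[!tr, , drop = FALSE], scaler)
    ytr <- y[tr]; yte <- y[!tr]
    for (i in seq_len(nrow(cells))) {
      fit <- .fitSVM(Ztr, ytr, cells$c[i], cells$g[i])
      acc[i] <- acc[i] + sum(.predictSVM(fit, Zte)$labels == yte)
    }
  }
  acc <- 100 * acc / length(y)
  # ties toward smaller c then smaller g: order rows accordingly, take the
  # first strict maximum
  ord <- order(cells$c, cells$g)
  best <- ord[which.max(acc[ord])]
  list(bestC = cells$c[best], bestG = cells$g[best],
       bestAccuracy = acc[best],
       cvTable = data.frame(c = cells$c, g = cells$g, accuracy = acc))
}

#' Train an RBF-SVM on latent scores
#'
#' Standardizes features (mean 0, sd 1 on the training data; parameters
#' stored for prediction) and fits a soft-margin RBF-kernel SVM with the
#' given hyperparameters. Zero-variance features get scale 1 with a warning.
#'
#' @param Z N-by-q training score matrix (or \linkS4class{LatentScores}).
#' @param y binary labels (0/1).
#' @param c soft-margin penalty (> 0).
#' @param g RBF kernel width (> 0).
#' @param cvAccuracy optional cross-validation accuracy to record.
#' @param foldsSeed optional fold seed to record.
#' @return a \linkS4class{TrainedClassifier}.
#' @export
trainClassifier <- function(Z, y, c, g, cvAccuracy = NA_real_,
                            foldsSeed = NA_integer_) {
  if (is(Z, "LatentScores")) Z <- Z@Z
  Z <- as.matrix(Z)
  y <- .checkBinaryLabels(y)
  stopifnot(nrow(Z) == length(y), c > 0, g > 0)
  scaler <- .fitScaler(Z)
  fit <- .fitSVM(.applyScaler(Z, scaler), y, c, g)
  new("TrainedClassifier", svm = fit, bestC = c, bestG = g,
      cvAccuracy = as.numeric(cvAccuracy),
      foldsSeed = as.integer(foldsSeed),
      scalerCenter = scaler$center, scalerScale = scaler$scale)
}

#' Run a cross-validated grid search and train the final classifier
#'
#' Convenience wrapper: \code{\link{svmGridSearch}} followed by
#' \code{\link{trainClassifier}} at the selected hyperparameters on the full
#' training set.
#'
#' @inheritParams svmGridSearch
#' @return a \linkS4class{TrainedClassifier}.
#' @export
trainWithGridSearch <- function(Z, y, cfg = svmConfig()) {
  gs <- svmGridSearch(Z, y, cfg)
  trainClassifier(Z, y, gs$bestC, gs$bestG,
                  cvAccuracy = gs$bestAccuracy, foldsSeed = cfg$seed)
}

#' Predict classes for new latent scores
#'
#' Applies the stored training standardization (never refitted) and the
#' fitted SVM. The signed decision value is oriented so that positive values
#' correspond to the positive (cancer) class; its sign always matches the
#' predicted label.
#'
#' @param object a \linkS4class{TrainedClassifier}.
#' @param newdata N-by-q matrix of scores (or \linkS4class{LatentScores}).
#' @return a list with integer \code{labels} (0/1) and numeric
#'   \code{decision} values.
#' @export
setMethod("predict", "TrainedClassifier", function(object, newdata) {
  if (is(newdata, "LatentScores")) newdata <- newdata@Z
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object@scalerCenter))
    stop("newdata has ", ncol(newdata), " features; classifier expects ",
         length(object@scalerCenter))
  Z <- .applyScaler(newdata,
                    list(center = object@scalerCenter,
                         scale = object@scalerScale))
  .predictSVM(object@svm, Z)
})
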