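#' @include AllGenerics.R
NULL

#' MassSpectrum: one sample's mass spectrum
#'
#' A single SELDI-TOF-like mass spectrum: a strictly increasing m/z axis
#' (Thomson/Da) with a matching intensity vector (arbitrary units), an
#' optional binary class label (1 = cancer/positive, 0 = healthy/negative,
#' \code{NA} = unlabeled) and a sample identifier.
#'
#' @slot mz numeric, strictly increasing m/z values, length >= 2.
#' @slot intensity numeric, same length as \code{mz}.
#' @slot label integer, \code{0L}, \code{1L} or \code{NA_integer_}.
#' @slot sampleId character scalar.
#' @exportClass MassSpectrum
setClass("MassSpectrum",
  representation(mz = "numeric", intensity = "numeric",
                 label = "integer", sampleId = "character"),
  prototype(label = NA_integer_, sampleId = NA_character_))

setValidity("MassSpectrum", function(object) {
  msg <- character()
  if (length(object@mz) != length(object@intensity))
    msg <- c(msg, "mz and intensity must have equal length")
  if (length(object@mz) < 2L)
    msg <- c(msg, "a spectrum needs at least 2 points")
  if (anyNA(object@mz) || is.unsorted(object@mz, strictly = TRUE))
    msg <- c(msg, "mz must be strictly increasing with no duplicates")
  if (!is.na(object@label) && !object@label %in% c(0L, 1L))
    msg <- c(msg, "label must be 0, 1 or NA")
  if (length(msg)) msg else TRUE
})

#' Create a MassSpectrum
#'
#' @param mz numeric vector of m/z values (will be kept as given; must be
#'   strictly increasing).
#' @param intensity numeric vector, same length.
#' @param label optional class label: \code{0}, \code{1} or \code{NA}.
#' @param sampleId optional sample identifier.
#' @return a \linkS4class{MassSpectrum}.
#' @examples
#' s <- MassSpectrum(mz = c(2000, 2001, 2002), intensity = c(0, 5, 1))
#' mz(s)
#' @export
MassSpectrum <- function(mz, intensity, label = NA, sampleId = NA_character_) {
  new("MassSpectrum", mz = as.numeric(mz), intensity = as.numeric(intensity),
      label = as.integer(label), sampleId = as.character(sampleId))
}

#' SpectrumSet: N samples on a shared m/z grid
#'
#' The working container of the pipeline: an N-by-d intensity matrix whose
#' rows are samples, the shared strictly increasing d-point m/z grid, a
#' binary label vector (\code{NA} allowed when unlabeled) and sample
#' identifiers. Supervised operations require exactly two label values.
#'
#' @slot grid numeric, shared m/z grid (length d, strictly increasing).
#' @slot X numeric matrix, N x d intensities.
#' @slot labels integer vector of length N (0/1/NA).
#' @slot sampleIds character vector of length N.
#' @exportClass SpectrumSet
setClass("SpectrumSet",
  representation(grid = "numeric", X = "matrix",
                 labels = "integer", sampleIds = "character"))

setValidity("SpectrumSet", function(object) {
  msg <- character()
  if (ncol(object@X) != length(object@grid))
    msg <- c(msg, "ncol(X) must equal length(grid)")
  if (anyNA(object@grid) || is.unsorted(object@grid, strictly = TRUE))
    msg <- c(msg, "grid must be strictly increasing")
  if (length(object@labels) != nrow(object@X))
    msg <- c(msg, "labels must have one entry per row of X")
  if (length(object@sampleIds) != nrow(object@X))
    msg <- c(msg, "sampleIds must have one entry per row of X")
  bad <- !is.na(object@labels) & !object@labels %in% c(0L, 1L)
  if (any(bad)) msg <- c(msg, "labels must be 0, 1 or NA")
  if (length(msg)) msg else TRUE
})

#' Create a SpectrumSet
#'
#' @param X numeric N-by-d matrix, one sample per row.
#' @param grid numeric shared m/z grid of length d.
#' @param labels binary labels (0/1/NA), recycled NA if missing.
#' @param sampleIds sample identifiers, autogenerated if missing.
#' @return a \linkS4class{SpectrumSet}.
#' @export
SpectrumSet <- function(X, grid, labels = NULL, sampleIds = NULL) {
  X <- as.matrix(X)
  if (is.null(labels)) labels <- rep(NA_integer_, nrow(X))
  if (is.null(sampleIds)) sampleIds <- paste0("S", seq_len(nrow(X)))
  new("SpectrumSet", X = X, grid = as.numeric(grid),
      labels = as.integer(labels), sampleIds = as.character(sampleIds))
}

#' PPCAModel: fitted probabilistic PCA parameters
#'
#' The Gaussian latent-variable model \eqn{s = W x + \mu + \epsilon} with
#' \eqn{x \sim N(0, I_q)} and isotropic noise
#' \eqn{\epsilon \sim N(0, \sigma^2 I_d)}, fitted by maximum likelihood.
#' The d-by-d model covariance \eqn{C = W W^T + \sigma^2 I} and the q-by-q
#' \eqn{M = W^T W + \sigma^2 I} are derived on demand, never stored.
#'
#' @slot W numeric d-by-q factor loading matrix.
#' @slot mu numeric d-vector mean.
#' @slot sigma2 numeric scalar noise variance, >= 0.
#' @slot q integer latent dimension, q < d.
#' @slot loglikTrace numeric per-iteration log-likelihood values (EM fits;
#'   empty for closed-form fits).
#' @slot nIter integer number of iterations used.
#' @slot converged logical convergence flag.
#' @slot method character, "em" or "eigen".
#' @exportClass PPCAModel
setClass("PPCAModel",
  representation(W = "matrix", mu = "numeric", sigma2 = "numeric",
                 q = "integer", loglikTrace = "numeric", nIter = "integer",
                 converged = "logical", method = "character"))

setValidity("PPCAModel", function(object) {
  msg <- character()
  if (object@sigma2 < 0) msg <- c(msg, "sigma2 must be >= 0")
  if (ncol(object@W) != object@q) msg <- c(msg, "ncol(W) must equal q")
  if (object@q >= nrow(object@W)) msg <- c(msg, "q must be < d")
  if (length(object@mu) != nrow(object@W))
    msg <- c(msg, "mu must have length d")
  if (identical(object@method, "em") &&
      length(object@loglikTrace) != object@nIter)
    msg <- c(msg, "loglikTrace length must equal nIter")
  tr <- object@loglikTrace
  if (length(tr) > 1L) {
    slack <- 1e-8 * pmax(abs(tr[-length(tr)]), 1)
    if (any(diff(tr) < -slack))
      msg <- c(msg, "log-likelihood trace must be non-decreasing (EM)")
  }
  if (length(msg)) msg else TRUE
})

#' PCAModel: classical principal component analysis fit
#'
#' Mean-centered eigendecomposition of the sample covariance (divisor N, the
#' same convention used by the PPCA likelihood), computed through the Gram
#' matrix / SVD when d >> N.
#'
#' @slot components numeric d-by-q orthonormal loading matrix.
#' @slot mu numeric d-vector mean.
#' @slot eigenvalues numeric q-vector of explained variances, non-increasing.
#' @slot allEigenvalues numeric vector of all computed covariance eigenvalues
#'   (length min(N-1, d) rank bound), used for cumulative-variance q selection.
#' @exportClass PCAModel
setClass("PCAModel",
  representation(components = "matrix", mu = "numeric",
                 eigenvalues = "numeric", allEigenvalues = "numeric"))

setValidity("PCAModel", function(object) {
  msg <- character()
  ev <- object@eigenvalues
  if (length(ev) != ncol(object@components))
    msg <- c(msg, "one eigenvalue per component required")
  if (any(ev < -1e-10)) msg <- c(msg, "eigenvalues must be >= 0")
  if (is.unsorted(rev(ev), strictly = FALSE) && length(ev) > 1L)
    msg <- c(msg, "eigenvalues must be non-increasing")
  G <- crossprod(object@components)
  if (max(abs(G - diag(ncol(G)))) > 1e-8)
    msg <- c(msg, "components must be orthonormal (1e-8)")
  if (length(msg)) msg else TRUE
})

#' LatentScores: latent coordinates of a set of samples
#'
#' @slot Z numeric N-by-q matrix of latent coordinates.
#' @slot mode character, \code{"posterior-mean"} or \code{"cross-projection"}.
#' @exportClass LatentScores
setClass("LatentScores",
  representation(Z = "matrix", mode = "character"))

#' TrainedClassifier: fitted RBF-SVM behind a feature scaler
#'
#' Wraps a fitted soft-margin RBF-kernel support vector machine together with
#' the hyperparameters selected by cross-validation and the per-feature
#' standardization learned on the training scores (applied verbatim, never
#' refitted, at prediction time).
#'
#' @slot svm the fitted \code{e1071::svm} object.
#' @slot bestC numeric selected penalty parameter c.
#' @slot bestG numeric selected RBF width g.
#' @slot cvAccuracy numeric best mean cross-validation accuracy (percent);
#'   \code{NA} when hyperparameters were supplied directly.
#' @slot foldsSeed integer fold-assignment seed (\code{NA} if not searched).
#' @slot scalerCenter numeric per-feature training means.
#' @slot scalerScale numeric per-feature training standard deviations
#'   (zero-variance features get scale 1).
#' @exportClass TrainedClassifier
setClass("TrainedClassifier",
  representation(svm = "ANY", bestC = "numeric", bestG = "numeric",
                 cvAccuracy = "numeric", foldsSeed = "integer",
                 scalerCenter = "numeric", scalerScale = "numeric"))

## ---- accessors ----

#' @rdname accessors
#' @export
setMethod("mz", "MassSpectrum", function(object) object@mz)

#' @rdname accessors
#' @export
setMethod("intensity", "MassSpectrum", function(object) object@intensity)

#' @rdname accessors
#' @export
setMethod("mzGrid", "SpectrumSet", function(object) object@grid)

#' @rdname accessors
#' @export
setMethod("intensityMatrix", "SpectrumSet", function(object) object@X)

#' @rdname accessors
#' @export
setMethod("classLabels", "SpectrumSet", function(object) object@labels)

#' @rdname accessors
#' @export
setMethod("classLabels", "MassSpectrum", function(object) object@label)

#' @rdname accessors
#' @export
setMethod("sampleIds", "SpectrumSet", function(object) object@sampleIds)

#' @rdname accessors
#' @export
setMethod("sampleIds", "MassSpectrum", function(object) object@sampleId)

#' @describeIn SpectrumSet-class number of samples and grid points.
#' @param x a \linkS4class{SpectrumSet}.
#' @export
setMethod("dim", "SpectrumSet", function(x) dim(x@X))

#' @rdname model-accessors
#' @export
setMethod("loadingMatrix", "PPCAModel", function(object) object@W)

#' @rdname model-accessors
#' @export
setMethod("loadingMatrix", "PCAModel", function(object) object@components)

#' @rdname model-accessors
#' @export
setMethod("modelCenter", "PPCAModel", function(object) object@mu)

#' @rdname model-accessors
#' @export
setMethod("modelCenter", "PCAModel", function(object) object@mu)

#' @rdname model-accessors
#' @export
setMethod("noiseVariance", "PPCAModel", function(object) object@sigma2)

#' @rdname model-accessors
#' @export
setMethod("latentDim", "PPCAModel", function(object) object@q)

#' @rdname model-accessors
#' @export
setMethod("latentDim", "PCAModel", function(object) ncol(object@components))

#' @rdname model-accessors
#' @export
setMethod("eigenValues", "PCAModel", function(object) object@eigenvalues)

#' @rdname model-accessors
#' @export
setMethod("logLikTrace", "PPCAModel", function(object) object@loglikTrace)

#' Scores matrix of a LatentScores object
#' @param object a \linkS4class{LatentScores}.
#' @return the N-by-q numeric score matrix.
#' @export
scoresMatrix <- function(object) {
  stopifnot(is(object, "LatentScores"))
  object@Z
}

#' Projection mode of a LatentScores object
#' @param object a \linkS4class{LatentScores}.
#' @return \code{"posterior-mean"} or \code{"cross-projection"}.
#' @export
scoreMode <- function(object) {
  stopifnot(is(object, "LatentScores"))
  object@mode
}

## ---- show methods ----

setMethod("show", "MassSpectrum", function(object) {
  cat("MassSpectrum", if (!is.na(object@sampleId)) sQuote(object@sampleId),
      "\n  ", length(object@mz), " points, m/z ",
      format(min(object@mz)), "-", format(max(object@mz)),
      "\n  label: ",
      if (is.na(object@label)) "unlabeled" else
        c("healthy (0)", "cancer (1)")[object@label + 1L],
      "\n", sep = "")
})

setMethod("show", "SpectrumSet", function(object) {
  n <- nrow(object@X)
  lab <- object@labels
  cat("SpectrumSet: ", n, " samples x ", length(object@grid),
      " grid points (m/z ", format(min(object@grid)), "-",
      format(max(object@grid)), ")\n", sep = "")
  if (all(is.na(lab))) cat("  unlabeled\n")
  else cat("  labels: ", sum(lab == 1L, na.rm = TRUE), " cancer, ",
           sum(lab == 0L, na.rm = TRUE), " healthy\n", sep = "")
})

setMethod("show", "PPCAModel", function(object) {
  cat("PPCAModel (", object@method, "): d = ", nrow(object@W),
      ", q = ", object@q, ", sigma2 = ", format(object@sigma2), "\n", sep = "")
  if (length(object@loglikTrace))
    cat("  EM: ", object@nIter, " iterations, ",
        if (object@converged) "converged" else "not converged",
        ", final log-likelihood ",
        format(utils::tail(object@loglikTrace, 1L)),
        "\n", sep = "")
})

setMethod("show", "PCAModel", function(object) {
  cat("PCAModel: d = ", nrow(object@components), ", q = ",
      ncol(object@components), "\n  leading eigenvalues: ",
      paste(format(utils::head(object@eigenvalues, 3L), digits = 4),
            collapse = ", "), "\n", sep = "")
})

setMethod("show", "LatentScores", function(object) {
  cat("LatentScores: ", nrow(object@Z), " samples x ", ncol(object@Z),
      " latent dimensions (", object@mode, ")\n", sep = "")
})

setMethod("show", "TrainedClassifier", function(object) {
  cat("TrainedClassifier: RBF-SVM, c = ", format(object@bestC),
      ", g = ", format(object@bestG), sep = "")
  if (!is.na(object@cvAccuracy))
    cat(", CV accuracy ", format(object@cvAccuracy, digits = 4), "%",
        sep = "")
  cat("\n  ", length(object@scalerCenter), " standardized features\n",
      sep = "")
})
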