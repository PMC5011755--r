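#' Accessor generics
#'
#' Accessors for the core classes: \code{mz} and \code{intensity} return a
#' spectrum's axis and signal, \code{mzGrid} and \code{intensityMatrix} the
#' shared grid and the samples-by-grid matrix of a \linkS4class{SpectrumSet},
#' \code{classLabels} the binary labels (1 = cancer/positive, 0 =
#' healthy/negative, \code{NA} when unlabeled) and \code{sampleIds} the sample
#' identifiers.
#'
#' @param object a \linkS4class{MassSpectrum}, \linkS4class{SpectrumSet} or
#'   model object.
#' @return the corresponding slot value.
#' @name accessors
#' @aliases mz intensity mzGrid intensityMatrix classLabels sampleIds
NULL

#' @rdname accessors
#' @export
setGeneric("mz", function(object) standardGeneric("mz"))

#' @rdname accessors
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))

#' @rdname accessors
#' @export
setGeneric("mzGrid", function(object) standardGeneric("mzGrid"))

#' @rdname accessors
#' @export
setGeneric("intensityMatrix", function(object) standardGeneric("intensityMatrix"))

#' @rdname accessors
#' @export
setGeneric("classLabels", function(object) standardGeneric("classLabels"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' Model accessor generics
#'
#' \code{loadingMatrix} returns the d-by-q factor loading (or principal axis)
#' matrix of a fitted dimension-reduction model, \code{modelCenter} its
#' d-vector mean, \code{noiseVariance} the isotropic noise variance of a
#' \linkS4class{PPCAModel}, \code{latentDim} the latent dimension q,
#' \code{eigenValues} the explained variances of a \linkS4class{PCAModel},
#' and \code{logLikTrace} the per-iteration log-likelihood trace of an EM fit.
#'
#' @param object a fitted \linkS4class{PPCAModel} or \linkS4class{PCAModel}.
#' @return the corresponding slot value.
#' @name model-accessors
#' @aliases loadingMatrix modelCenter noiseVariance latentDim eigenValues logLikTrace
NULL

#' @rdname model-accessors
#' @export
setGeneric("loadingMatrix", function(object) standardGeneric("loadingMatrix"))

#' @rdname model-accessors
#' @export
setGeneric("modelCenter", function(object) standardGeneric("modelCenter"))

#' @rdname model-accessors
#' @export
setGeneric("noiseVariance", function(object) standardGeneric("noiseVariance"))

#' @rdname model-accessors
#' @export
setGeneric("latentDim", function(object) standardGeneric("latentDim"))

#' @rdname model-accessors
#' @export
setGeneric("eigenValues", function(object) standardGeneric("eigenValues"))

#' @rdname model-accessors
#' @export
setGeneric("logLikTrace", function(object) standardGeneric("logLikTrace"))

#' Project observations into the latent space
#'
#' Computes latent coordinates for new observations under a fitted
#' \linkS4class{PPCAModel} or \linkS4class{PCAModel}.
#'
#' For PPCA two projection conventions are offered. The default,
#' \code{"posterior-mean"}, is the posterior expectation of the latent
#' variable, \eqn{z_n = M^{-1} W^T (s_n - \mu)} with
#' \eqn{M = W^T W + \sigma^2 I}. The alternative \code{"cross-projection"}
#' omits the \eqn{M^{-1}} factor, \eqn{z_n = W^T (s_n - \mu)}; both span the
#' same subspace and coincide when \eqn{\sigma^2 = 0} and \eqn{W^T W = I}.
#' PCA models always use the orthonormal cross-projection.
#'
#' @param model a fitted \linkS4class{PPCAModel} or \linkS4class{PCAModel}.
#' @param X an N-by-d numeric matrix (rows = samples) or a
#'   \linkS4class{SpectrumSet} on a d-point grid.
#' @param mode \code{"posterior-mean"} (default) or \code{"cross-projection"}.
#' @return a \linkS4class{LatentScores} object.
#' @export
setGeneric("latentScores", function(model, X, mode = "posterior-mean")
  standardGeneric("latentScores"))

#' Reconstruct observations from latent scores
#'
#' Maps latent coordinates back into observation space via
#' \eqn{\tilde{s}_n = W (W^T W)^{-1} z_n + \mu}. For cross-projection scores
#' this is the orthogonal projection of the original observation onto
#' \eqn{\mu + \mathrm{span}(W)}.
#'
#' @param model the fitted model the scores came from.
#' @param scores a \linkS4class{LatentScores} object (or N-by-q matrix).
#' @return an N-by-d numeric matrix.
#' @export
setGeneric("reconstructSamples", function(model, scores)
  standardGeneric("reconstructSamples"))

#' Marginal log-likelihood of data under a PPCA model
#'
#' Evaluates \eqn{L = -\frac{N}{2}\left[d\ln 2\pi + \ln|C| + tr(C^{-1}U)\right]}
#' with \eqn{C = W W^T + \sigma^2 I} and \eqn{U} the covariance of \code{X}
#' about the model center. The determinant and trace are evaluated through the
#' q-by-q matrix \eqn{M = W^T W + \sigma^2 I} (matrix determinant lemma /
#' Woodbury identity), so the d-by-d matrix \eqn{C} is never formed.
#'
#' @param model a fitted \linkS4class{PPCAModel}.
#' @param X an N-by-d matrix or \linkS4class{SpectrumSet}.
#' @return a numeric scalar; \code{-Inf} with attribute \code{degenerate=TRUE}
#'   when \eqn{\sigma^2 = 0} while \eqn{q < d} (singular model).
#' @export
setGeneric("logLikelihood", function(model, X) standardGeneric("logLikelihood"))
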