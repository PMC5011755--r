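# Probabilistic PCA (Tipping-Bishop latent-variable model) fitted either by
# EM or by the closed-form eigendecomposition maximum-likelihood solution,
# plus classical PCA. All covariance-level algebra is routed through the
# N x N Gram matrix when d > N, so a 15000-dimensional fit on ~200 samples
# costs a couple of large matrix products, never a d x d eigenproblem.

.asMatrixInput <- function(X) {
  if (is(X, "SpectrumSet")) X <- intensityMatrix(X)
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("X must be finite (no NA/NaN/Inf)")
  X
}

# log-likelihood of the model (W, sigma2) given trU (trace of sample
# covariance) and WtUW = W^T U W, all q-level quantities.
.ppcaLogLik <- function(N, d, WtW, sigma2, trU, WtUW) {
  q <- ncol(WtW)
  M <- WtW + diag(sigma2, q)
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch) || sigma2 <= 0) return(-Inf)
  logdetM <- 2 * sum(log(diag(ch)))
  Minv <- chol2inv(ch)
  logdetC <- (d - q) * log(sigma2) + logdetM
  trCinvU <- (trU - sum(Minv * WtUW)) / sigma2
  -(N / 2) * (d * log(2 * pi) + logdetC + trCinvU)
}

#' Fit probabilistic PCA
#'
#' Fits the latent-variable model \eqn{s = W x + \mu + \epsilon},
#' \eqn{x \sim N(0, I_q)}, \eqn{\epsilon \sim N(0, \sigma^2 I_d)} by maximum
#' likelihood. \code{method = "em"} iterates the EM updates
#' \deqn{\tilde{W} = U W (\sigma^2 I + M^{-1} W^T U W)^{-1}, \quad
#'       \tilde{\sigma}^2 = \frac{1}{d} tr(U - U W M^{-1} \tilde{W}^T)}
#' with \eqn{U} the sample covariance (divisor N) and
#' \eqn{M = W^T W + \sigma^2 I}, stopping when the relative change of the
#' log-likelihood falls below \code{tol} or \code{maxIter} is reached; the
#' log-likelihood is non-decreasing across iterations and a decrease beyond
#' numerical slack raises an internal-consistency error.
#' \code{method = "eigen"} computes the known global optimum directly:
#' \eqn{\sigma^2} is the mean of the d-q smallest covariance eigenvalues and
#' \eqn{W = U_q (\Lambda_q - \sigma^2 I)^{1/2}}.
#'
#' When d > N all computation runs through the N x N Gram matrix; after the
#' first EM step the loading matrix lies in the span of the centered data,
#' so iterations cost O(N^2 q) regardless of d.
#'
#' @param X N-by-d numeric matrix (rows = samples) or
#'   \linkS4class{SpectrumSet}.
#' @param q latent dimension, \code{1 <= q < min(N, d)}.
#' @param method \code{"em"} (default) or \code{"eigen"}.
#' @param tol relative log-likelihood convergence tolerance for EM.
#' @param maxIter EM iteration cap.
#' @param seed RNG seed for the random Gaussian initialization of W
#'   (required for EM; recorded in the fit).
#' @return a \linkS4class{PPCAModel}.
#' @examples
#' X <- simulateLatentGaussian(n = 200, d = 10, q = 2, sigma2 = 0.3,
#'                             seed = 1)$S
#' fitPPCA(X, q = 2, seed = 1)
#' @export
fitPPCA <- function(X, q, method = c("em", "eigen"), tol = 1e-7,
                    maxIter = 500L, seed = 1L) {
  method <- match.arg(method)
  X <- .asMatrixInput(X)
  N <- nrow(X); d <- ncol(X)
  q <- as.integer(q)
  if (N < 2L) stop("need at least 2 samples")
  if (q < 1L || q >= min(N, d))
    stop("q must satisfy 1 <= q < min(N, d) = ", min(N, d))
  mu <- colMeans(X)
  Cc <- sweep(X, 2L, mu, "-")
  if (method == "eigen") return(.ppcaEigen(Cc, mu, q))
  if (d > N) .ppcaEMGram(Cc, mu, q, tol, as.integer(maxIter), seed)
  else .ppcaEMDense(Cc, mu, q, tol, as.integer(maxIter), seed)
}

.sigmaFloor <- 1e-300

.newPPCA <- function(W, mu, sigma2, trace, converged, method) {
  new("PPCAModel", W = W, mu = mu, sigma2 = max(sigma2, 0),
      q = ncol(W), loglikTrace = trace, nIter = length(trace),
      converged = converged, method = method)
}

.checkMonotone <- function(trace) {
  if (length(trace) > 1L) {
    prev <- trace[-length(trace)]
    slack <- 1e-8 * pmax(abs(prev), 1)
    drop <- diff(trace) < -slack
    drop[!is.finite(prev)] <- FALSE
    if (any(drop))
      stop("internal consistency failure: EM log-likelihood decreased at ",
           "iteration ", which(drop)[1L] + 1L)
  }
}

.ppcaEMDense <- function(Cc, mu, q, tol, maxIter, seed) {
  N <- nrow(Cc); d <- ncol(Cc)
  U <- crossprod(Cc) / N
  trU <- sum(diag(U))
  sdX <- sqrt(max(trU / d, .Machine$double.eps))
  W <- .withSeed(seed, matrix(stats::rnorm(d * q, sd = sdX), d, q))
  sigma2 <- max(trU / d, .sigmaFloor)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    WtW <- crossprod(W)
    UW <- U %*% W
    WtUW <- crossprod(W, UW)
    ll <- .ppcaLogLik(N, d, WtW, sigma2, trU, WtUW)
    trace <- c(trace, ll)
    if (it > 1L && is.finite(ll) && is.finite(trace[it - 1L]) &&
        abs(ll - trace[it - 1L]) < tol * abs(trace[it - 1L])) {
      converged <- TRUE
      break
    }
    M <- WtW + diag(sigma2, q)
    Minv <- chol2inv(chol(M))
    inner <- diag(sigma2, q) + Minv %*% WtUW
    Wnew <- UW %*% solve(inner)
    sigma2 <- max((trU - sum((UW %*% Minv) * Wnew)) / d, .sigmaFloor)
    W <- Wnew
    if (sigma2 <= 1e-9 * trU / d && trU > 0) {
      # residual variance has collapsed (q at or near the data rank); the
      # likelihood is unbounded there and further evaluation is pure
      # cancellation noise
      converged <- TRUE
      break
    }
  }
  .checkMonotone(trace)
  .newPPCA(W, mu, sigma2, trace, converged, "em")
}

.ppcaEMGram <- function(Cc, mu, q, tol, maxIter, seed) {
  N <- nrow(Cc); d <- ncol(Cc)
  K <- tcrossprod(Cc)            # N x N Gram of centered rows
  trU <- sum(diag(K)) / N
  sdX <- sqrt(max(trU / d, .Machine$double.eps))
  W0 <- .withSeed(seed, matrix(stats::rnorm(d * q, sd = sdX), d, q))
  sigma2 <- max(trU / d, .sigmaFloor)
  trace <- numeric(0)
  converged <- FALSE
  # state: either the initial dense W0 (first pass) or A with W = t(Cc) %*% A
  A <- NULL
  P0 <- Cc %*% W0                # N x q
  WtW <- crossprod(W0)
  WtUW <- crossprod(P0) / N
  for (it in seq_len(maxIter)) {
    ll <- .ppcaLogLik(N, d, WtW, sigma2, trU, WtUW)
    trace <- c(trace, ll)
    if (it > 1L && is.finite(ll) && is.finite(trace[it - 1L]) &&
        abs(ll - trace[it - 1L]) < tol * abs(trace[it - 1L])) {
      converged <- TRUE
      break
    }
    M <- WtW + diag(sigma2, q)
    Minv <- chol2inv(chol(M))
    inner <- diag(sigma2, q) + Minv %*% WtUW
    innerInv <- solve(inner)
    if (is.null(A)) {
      # U W0 = t(Cc) (P0 / N): the update lands in the data span
      Anew <- (P0 / N) %*% innerInv
      # tr(M^-1 Wnew^T U W0) with Wnew^T U W0 = (K Anew)^T P0 / N
      KAnew <- K %*% Anew
      sigma2 <- max((trU - sum(Minv * (crossprod(KAnew, P0) / N))) / d,
                    .sigmaFloor)
    } else {
      KA <- K %*% A
      Anew <- (KA / N) %*% innerInv
      KAnew <- K %*% Anew
      sigma2 <- max((trU - sum(Minv * (crossprod(KAnew, KA) / N))) / d,
                    .sigmaFloor)
    }
    A <- Anew
    KA <- KAnew
    WtW <- crossprod(A, KA)
    WtUW <- crossprod(KA) / N
    if (sigma2 <= 1e-9 * trU / d && trU > 0) {
      # degenerate residual variance: see the dense path
      converged <- TRUE
      break
    }
  }
  .checkMonotone(trace)
  W <- if (is.null(A)) W0 else crossprod(Cc, A)
  .newPPCA(W, mu, sigma2, trace, converged, "em")
}

# Closed-form ML solution via eigendecomposition (Gram route for d > N).
.ppcaEigen <- function(Cc, mu, q) {
  N <- nrow(Cc); d <- ncol(Cc)
  if (d > N) {
    K <- tcrossprod(Cc) / N
    trU <- sum(diag(K))
    eg <- eigen(K, symmetric = TRUE)
    lam <- pmax(eg$values, 0)
    # top-q eigenvectors of U from those of K: u_i = t(Cc) v_i / sqrt(N lam_i)
    lamQ <- lam[seq_len(q)]
    if (any(lamQ <= 0))
      stop("data rank is below q = ", q, "; reduce q")
    Uq <- crossprod(Cc, eg$vectors[, seq_len(q), drop = FALSE])
    Uq <- sweep(Uq, 2L, sqrt(N * lamQ), "/")
  } else {
    U <- crossprod(Cc) / N
    trU <- sum(diag(U))
    eg <- eigen(U, symmetric = TRUE)
    lam <- pmax(eg$values, 0)
    lamQ <- lam[seq_len(q)]
    Uq <- eg$vectors[, seq_len(q), drop = FALSE]
  }
  sigma2 <- max((trU - sum(lamQ)) / (d - q), 0)
  W <- sweep(Uq, 2L, sqrt(pmax(lamQ - sigma2, 0)), "*")
  # Exact likelihood at the optimum, evaluated from the eigenvalues:
  # ln|C| = sum_{i<=q} ln lam_i + (d-q) ln sigma2 ; tr(C^-1 U) = q + (trU - sum lamQ)/sigma2
  ll <- if (sigma2 > 0)
    -(N / 2) * (d * log(2 * pi) + sum(log(lamQ)) + (d - q) * log(sigma2) +
                  q + (trU - sum(lamQ)) / sigma2)
  else -Inf
  m <- .newPPCA(W, mu, sigma2, numeric(0), TRUE, "eigen")
  attr(m, "maxLogLik") <- ll
  m
}

## ---- projection / reconstruction / likelihood ----

#' @rdname latentScores
#' @export
setMethod("latentScores", "PPCAModel", function(model, X,
                                                mode = "posterior-mean") {
  mode <- match.arg(mode, c("posterior-mean", "cross-projection"))
  X <- .asMatrixInput(X)
  if (ncol(X) != nrow(model@W))
    stop("X has ", ncol(X), " columns but the model dimension is ",
         nrow(model@W))
  Cc <- sweep(X, 2L, model@mu, "-")
  Z <- Cc %*% model@W
  if (mode == "posterior-mean") {
    M <- crossprod(model@W) + diag(model@sigma2, model@q)
    Z <- Z %*% chol2inv(chol(M))
  }
  new("LatentScores", Z = Z, mode = mode)
})

#' @rdname latentScores
#' @export
setMethod("latentScores", "PCAModel", function(model, X,
                                               mode = "cross-projection") {
  X <- .asMatrixInput(X)
  if (ncol(X) != nrow(model@components))
    stop("X has ", ncol(X), " columns but the model dimension is ",
         nrow(model@components))
  Z <- sweep(X, 2L, model@mu, "-") %*% model@components
  new("LatentScores", Z = Z, mode = "cross-projection")
})

.reconstruct <- function(W, mu, Z) {
  WtW <- crossprod(W)
  ch <- tryCatch(chol(WtW), error = function(e) NULL)
  if (is.null(ch)) {
    r <- qr(W)$rank
    stop("W^T W is rank deficient (effective rank ", r, " < ", ncol(W),
         "); cannot reconstruct")
  }
  sweep(Z %*% chol2inv(ch) %*% t(W), 2L, mu, "+")
}

#' @rdname reconstructSamples
#' @export
setMethod("reconstructSamples", "PPCAModel", function(model, scores) {
  Z <- if (is(scores, "LatentScores")) scores@Z else as.matrix(scores)
  if (ncol(Z) != model@q) stop("scores have wrong latent dimension")
  .reconstruct(model@W, model@mu, Z)
})

#' @rdname reconstructSamples
#' @export
setMethod("reconstructSamples", "PCAModel", function(model, scores) {
  Z <- if (is(scores, "LatentScores")) scores@Z else as.matrix(scores)
  if (ncol(Z) != ncol(model@components))
    stop("scores have wrong latent dimension")
  .reconstruct(model@components, model@mu, Z)
})

#' @rdname logLikelihood
#' @export
setMethod("logLikelihood", "PPCAModel", function(model, X) {
  X <- .asMatrixInput(X)
  d <- nrow(model@W)
  if (ncol(X) != d) stop("X has wrong dimension")
  N <- nrow(X)
  Cc <- sweep(X, 2L, model@mu, "-")
  trU <- sum(Cc^2) / N
  if (model@sigma2 <= 0 && model@q < d) {
    out <- -Inf
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  P <- Cc %*% model@W
  WtUW <- crossprod(P) / N
  .ppcaLogLik(N, d, crossprod(model@W), model@sigma2, trU, WtUW)
})

## ---- classical PCA ----

#' Fit classical PCA
#'
#' Mean-centered principal component analysis with covariance divisor N (the
#' same convention as the PPCA likelihood). For d > N the decomposition runs
#' through the N x N Gram matrix. All nonzero covariance eigenvalues are
#' retained in the fit (slot \code{allEigenvalues}) so that
#' \code{\link{chooseLatentDim}} can be applied to the training spectrum
#' of variances.
#'
#' @param X N-by-d matrix or \linkS4class{SpectrumSet}.
#' @param q number of components, \code{1 <= q <= min(N - 1, d)}.
#' @return a \linkS4class{PCAModel}.
#' @export
fitPCA <- function(X, q) {
  X <- .asMatrixInput(X)
  N <- nrow(X); d <- ncol(X)
  q <- as.integer(q)
  if (N < 2L) stop("need at least 2 samples")
  if (q < 1L || q > min(N - 1L, d))
    stop("q must satisfy 1 <= q <= min(N-1, d) = ", min(N - 1L, d))
  mu <- colMeans(X)
  Cc <- sweep(X, 2L, mu, "-")
  if (d > N) {
    K <- tcrossprod(Cc) / N
    eg <- eigen(K, symmetric = TRUE)
    lam <- pmax(eg$values, 0)
    keep <- min(N - 1L, d)
    lamAll <- lam[seq_len(keep)]
    lamQ <- lamAll[seq_len(q)]
    if (any(lamQ <= 0)) stop("data rank is below q = ", q)
    V <- crossprod(Cc, eg$vectors[, seq_len(q), drop = FALSE])
    V <- sweep(V, 2L, sqrt(N * lamQ), "/")
  } else {
    U <- crossprod(Cc) / N
    eg <- eigen(U, symmetric = TRUE)
    lam <- pmax(eg$values, 0)
    lamAll <- lam
    lamQ <- lam[seq_len(q)]
    V <- eg$vectors[, seq_len(q), drop = FALSE]
  }
  new("PCAModel", components = V, mu = mu, eigenvalues = lamQ,
      allEigenvalues = lamAll)
}

#' Choose the latent dimension by cumulative explained variance
#'
#' Returns the smallest q such that the top-q eigenvalues account for at
#' least \code{threshold} of the total variance (default 99.99 percent, the
#' conventional near-lossless cut for preprocessed SELDI profiles).
#'
#' @param eigenvalues non-negative, non-increasing variance spectrum (e.g.
#'   the \code{allEigenvalues} of a \code{\link{fitPCA}} fit).
#' @param threshold required cumulative fraction, in (0, 1].
#' @return integer q.
#' @examples
#' chooseLatentDim(c(9, 1), 0.9)   # 1
#' chooseLatentDim(c(9, 1), 0.91)  # 2
#' @export
chooseLatentDim <- function(eigenvalues, threshold = 0.9999) {
  stopifnot(threshold > 0, threshold <= 1)
  ev <- as.numeric(eigenvalues)
  if (any(ev < -1e-12 * max(abs(ev)))) stop("eigenvalues must be >= 0")
  ev <- pmax(ev, 0)
  if (is.unsorted(rev(ev))) stop("eigenvalues must be non-increasing")
  tot <- sum(ev)
  if (tot <= 0) stop("all eigenvalues are zero")
  as.integer(which(cumsum(ev) / tot >= threshold - 1e-12)[1L])
}
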