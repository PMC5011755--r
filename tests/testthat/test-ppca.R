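# Probabilistic PCA: EM fit, closed-form oracle, projections,
# reconstruction, likelihood, classical PCA, q selection.

test_that("closed-form fit recovers the known solution on diagonal data", {
  # covariance diag(4,1,1): sigma2 -> mean of the two smallest eigenvalues
  # = 1, W direction -> first axis, ||W||^2 -> 4 - 1 = 3
  set.seed(5)
  n <- 20000
  X <- cbind(rnorm(n, 0, 2), rnorm(n, 0, 1), rnorm(n, 0, 1))
  m <- fitPPCA(X, q = 1, method = "eigen")
  expect_equal(noiseVariance(m), 1, tolerance = 0.05)
  W <- loadingMatrix(m)
  expect_equal(sum(W^2), 3, tolerance = 0.1)
  expect_gt(abs(W[1, 1]) / sqrt(sum(W^2)), 0.99)

  # q = d-1 on isotropic-ish data: sigma2 equals the smallest eigenvalue
  m2 <- fitPPCA(X, q = 2, method = "eigen")
  ev <- eigen(crossprod(sweep(X, 2, colMeans(X))) / n,
              symmetric = TRUE, only.values = TRUE)$values
  expect_equal(noiseVariance(m2), min(ev), tolerance = 1e-10)
})

test_that("EM matches the closed-form global optimum on small instances", {
  for (seed in 1:3) {
    g <- simulateLatentGaussian(n = 300, d = 25, q = 3, sigma2 = 0.4,
                                seed = seed)
    em <- fitPPCA(g$S, 3, method = "em", tol = 1e-10, maxIter = 3000,
                  seed = seed + 100)
    cf <- fitPPCA(g$S, 3, method = "eigen")
    expect_equal(noiseVariance(em), noiseVariance(cf), tolerance = 1e-4)
    expect_lt(subspaceAngle(loadingMatrix(em), loadingMatrix(cf)), 1e-3)
    # the closed form attains the global maximum of the likelihood
    expect_gte(attr(cf, "maxLogLik") + 1e-6,
               tail(logLikTrace(em), 1))
  }
})

test_that("EM recovers generative parameters (sigma2 within 10%, subspace < 5 deg)", {
  g <- simulateLatentGaussian(n = 2000, d = 20, q = 3, sigma2 = 0.5,
                              seed = 42)
  em <- fitPPCA(g$S, 3, seed = 7)
  expect_lt(abs(noiseVariance(em) - 0.5) / 0.5, 0.10)
  expect_lt(subspaceAngle(loadingMatrix(em), g$W) * 180 / pi, 5)
})

test_that("EM log-likelihood trace is non-decreasing and evaluated correctly", {
  g <- simulateLatentGaussian(n = 100, d = 12, q = 2, sigma2 = 0.8,
                              seed = 2)
  em <- fitPPCA(g$S, 2, seed = 3)
  tr <- logLikTrace(em)
  expect_length(tr, em@nIter)
  finite <- is.finite(tr)
  expect_true(all(diff(tr[finite]) >= -1e-8 * pmax(abs(tr[finite][-sum(finite)]), 1)))
  # the reported trace endpoint equals an independent evaluation
  expect_equal(logLikelihood(em, g$S), tail(tr, 1), tolerance = 1e-10)
})

test_that("the Gram-space EM path agrees with the dense path (d > N)", {
  g <- simulateLatentGaussian(n = 40, d = 200, q = 3, sigma2 = 0.3,
                              seed = 8)
  gramFit <- fitPPCA(g$S, 3, seed = 5, tol = 1e-10, maxIter = 2000)
  cf <- fitPPCA(g$S, 3, method = "eigen")
  expect_equal(noiseVariance(gramFit), noiseVariance(cf), tolerance = 1e-4)
  expect_lt(subspaceAngle(loadingMatrix(gramFit), loadingMatrix(cf)), 1e-3)
})

test_that("degenerate zero-variance data drive sigma2 to zero", {
  X <- matrix(rep(c(1, 2, 3, 4), each = 5), nrow = 5, byrow = FALSE)
  m <- fitPPCA(X, 1, seed = 1, maxIter = 20)
  expect_lt(noiseVariance(m), 1e-12)
  tr <- logLikTrace(m)
  # trace settles immediately: constant after the first update
  expect_true(all(abs(diff(tr[-1])) < 1e-6 * abs(tr[2])))
})

test_that("posterior-mean scores match the brute-force linear solve", {
  g <- simulateLatentGaussian(n = 30, d = 5, q = 2, sigma2 = 0.6, seed = 21)
  m <- fitPPCA(g$S, 2, seed = 4)
  Z <- scoresMatrix(latentScores(m, g$S))
  W <- loadingMatrix(m)
  Zb <- t(solve(crossprod(W) + diag(noiseVariance(m), 2),
                t(sweep(g$S, 2, modelCenter(m)) %*% W)))
  expect_equal(Z, Zb, tolerance = 1e-10)

  # centering: the mean row maps to 0 in both modes
  mu <- matrix(modelCenter(m), 1)
  expect_equal(scoresMatrix(latentScores(m, mu))[1, ], c(0, 0))
  expect_equal(scoresMatrix(latentScores(m, mu,
                                         mode = "cross-projection"))[1, ],
               c(0, 0))
  expect_error(latentScores(m, g$S[, 1:3]), "dimension|columns")
})

test_that("reconstruction is the projection onto the model subspace", {
  g <- simulateLatentGaussian(n = 25, d = 8, q = 3, sigma2 = 0.5, seed = 13)
  m <- fitPPCA(g$S, 3, seed = 2)
  W <- loadingMatrix(m); mu <- modelCenter(m)

  # zero scores reconstruct to mu
  rec0 <- reconstructSamples(m, matrix(0, 2, 3))
  expect_equal(rec0, rbind(mu, mu), ignore_attr = TRUE)

  # points exactly in mu + span(W) are reproduced from cross-projection
  A <- matrix(rnorm(6, 2), 2, 3)
  pts <- sweep(A %*% t(W), 2, mu, "+")
  z <- latentScores(m, pts, mode = "cross-projection")
  expect_equal(reconstructSamples(m, z), pts, tolerance = 1e-8)

  # explicit projector oracle for arbitrary points
  P <- W %*% solve(crossprod(W)) %*% t(W)
  zc <- latentScores(m, g$S, mode = "cross-projection")
  expect_equal(reconstructSamples(m, zc),
               sweep(sweep(g$S, 2, mu) %*% P, 2, mu, "+"),
               tolerance = 1e-8)
})

test_that("reconstruction error is non-increasing in q (nested fits)", {
  g <- simulateLatentGaussian(n = 60, d = 15, q = 5, sigma2 = 0.4, seed = 6)
  errs <- sapply(1:8, function(qq) {
    m <- fitPPCA(g$S, qq, method = "eigen")
    z <- latentScores(m, g$S, mode = "cross-projection")
    sqrt(sum((g$S - reconstructSamples(m, z))^2))
  })
  expect_true(all(diff(errs) <= 1e-8))
})

test_that("log-likelihood matches closed-form entropy and the naive form", {
  # W ~ 0, sigma2 = 1, standard normal data: L/N ~ -(1/2)(ln 2pi + 1)
  set.seed(17)
  X <- matrix(rnorm(1e4), ncol = 1)
  m <- new("PPCAModel", W = matrix(0, 1, 0), mu = 0, sigma2 = 1, q = 0L,
           loglikTrace = numeric(0), nIter = 0L, converged = TRUE,
           method = "eigen")
  # q = 0 is outside the fitting contract; evaluate via a 2-d embedding
  X2 <- cbind(X, rnorm(1e4))
  m2 <- new("PPCAModel", W = matrix(c(0, 0), 2, 1), mu = c(0, 0),
            sigma2 = 1, q = 1L, loglikTrace = numeric(0), nIter = 0L,
            converged = TRUE, method = "eigen")
  ll <- logLikelihood(m2, X2)
  expect_equal(ll / 1e4, -(log(2 * pi) + 1), tolerance = 0.02)

  # additivity: duplicating the data doubles L
  lld <- logLikelihood(m2, rbind(X2, X2))
  expect_equal(lld, 2 * ll, tolerance = 1e-10)

  # stable q-form equals the naive d x d evaluation on a d = 30 toy
  g <- simulateLatentGaussian(n = 50, d = 30, q = 4, sigma2 = 0.7, seed = 9)
  m3 <- fitPPCA(g$S, 4, method = "eigen")
  W <- loadingMatrix(m3); s2 <- noiseVariance(m3); mu <- modelCenter(m3)
  C <- W %*% t(W) + diag(s2, 30)
  Cc <- sweep(g$S, 2, mu)
  U <- crossprod(Cc) / nrow(Cc)
  naive <- -(nrow(Cc) / 2) * (30 * log(2 * pi) +
    determinant(C, logarithm = TRUE)$modulus[1] + sum(solve(C) * U))
  expect_equal(logLikelihood(m3, g$S), naive, tolerance = 1e-6)

  # sigma2 = 0 with q < d is flagged, not crashed
  m0 <- new("PPCAModel", W = matrix(c(1, 0), 2, 1), mu = c(0, 0),
            sigma2 = 0, q = 1L, loglikTrace = numeric(0), nIter = 0L,
            converged = TRUE, method = "eigen")
  l0 <- logLikelihood(m0, X2)
  expect_identical(as.numeric(l0), -Inf)
  expect_true(attr(l0, "degenerate"))
})

test_that("input validation catches bad q and non-finite data", {
  g <- simulateLatentGaussian(n = 10, d = 5, q = 2, sigma2 = 0.1, seed = 1)
  expect_error(fitPPCA(g$S, 5, seed = 1), "q must")
  expect_error(fitPPCA(g$S, 0, seed = 1), "q must")
  Xb <- g$S; Xb[1, 1] <- NA
  expect_error(fitPPCA(Xb, 2, seed = 1), "finite")
})

test_that("classical PCA: orthonormal components, degenerate line, PPCA limit", {
  # data on a 1-D line in 3-D: first eigenvalue carries all variance
  t <- seq(-1, 1, length.out = 40)
  X <- cbind(2 * t, -t, 0.5 * t) + 5
  p <- fitPCA(X, 2)
  ev <- eigenValues(p)
  expect_gt(ev[1] / sum(p@allEigenvalues), 1 - 1e-12)
  expect_lt(ev[2], 1e-12)

  # orthonormality
  G <- crossprod(loadingMatrix(p))
  expect_equal(G, diag(2), tolerance = 1e-8)

  # Gram route (d > N) agrees with the dense route
  g <- simulateLatentGaussian(n = 20, d = 100, q = 3, sigma2 = 0.2, seed = 3)
  pg <- fitPCA(g$S, 3)
  Udense <- crossprod(sweep(g$S, 2, colMeans(g$S))) / 20
  egd <- eigen(Udense, symmetric = TRUE)
  expect_equal(eigenValues(pg), egd$values[1:3], tolerance = 1e-8)
  expect_lt(subspaceAngle(loadingMatrix(pg), egd$vectors[, 1:3]), 1e-6)

  # PPCA scores converge to scaled PCA scores as sigma2 -> 0
  g2 <- simulateLatentGaussian(n = 200, d = 10, q = 2, sigma2 = 1e-6,
                               seed = 12)
  pp <- fitPPCA(g2$S, 2, method = "eigen")
  pc <- fitPCA(g2$S, 2)
  expect_lt(subspaceAngle(loadingMatrix(pp), loadingMatrix(pc)), 1e-3)
  Zp <- scoresMatrix(latentScores(pp, g2$S))
  Zc <- scoresMatrix(latentScores(pc, g2$S))
  # posterior-mean PPCA scores = D^-1/2-scaled, possibly rotated PCA scores;
  # compare after per-column scale alignment of the aligned bases
  cor0 <- abs(stats::cancor(Zp, Zc)$cor)
  expect_true(all(cor0 > 1 - 1e-6))
})

test_that("chooseLatentDim implements the cumulative-variance rule", {
  expect_equal(chooseLatentDim(c(9, 1), 0.9), 1L)
  expect_equal(chooseLatentDim(c(9, 1), 0.91), 2L)
  expect_equal(chooseLatentDim(c(1, 1, 1, 1), 0.9999), 4L)
  expect_equal(chooseLatentDim(c(5, 3, 1, 1), 1), 4L)
  expect_error(chooseLatentDim(c(0, 0)), "zero")
  expect_error(chooseLatentDim(c(1, 2)), "non-increasing")
})
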