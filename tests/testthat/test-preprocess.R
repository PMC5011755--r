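# Preprocessing chain: resampling, baseline, denoising, alignment,
# normalization, and the composed pipeline.

test_that("sliding minimum matches the brute-force oracle", {
  set.seed(3)
  x <- rnorm(257)
  for (w in c(3L, 7L, 21L)) {
    h <- (w - 1L) %/% 2L
    brute <- sapply(seq_along(x), function(i)
      min(x[max(1L, i - h):min(length(x), i + h)]))
    expect_equal(msppca:::.runningMin(x, w), brute)
  }
})

test_that("resample does linear interpolation with zero fill outside", {
  cfg <- preprocessConfig(gridLo = 2000, gridHi = 10000, gridN = 5,
                          doBaseline = FALSE)
  s <- MassSpectrum(c(2000, 10000), c(0, 8000))
  r <- resampleSpectrum(s, cfg)
  expect_equal(mz(r), c(2000, 4000, 6000, 8000, 10000))
  expect_equal(intensity(r), c(0, 2000, 4000, 6000, 8000))

  # partial support: outside regions are zero
  s2 <- MassSpectrum(c(4000, 6000), c(2, 2))
  expect_equal(intensity(resampleSpectrum(s2, cfg)), c(0, 2, 2, 0, 0))

  # no overlap errors
  s3 <- MassSpectrum(c(100, 200), c(1, 1))
  expect_error(resampleSpectrum(s3, cfg), "overlap")
})

test_that("resample is idempotent on the target grid", {
  cfg <- preprocessConfig(gridN = 50)
  grid <- seq(cfg$gridLo, cfg$gridHi, length.out = 50)
  s <- MassSpectrum(grid, sqrt(seq_len(50)))
  expect_identical(intensity(resampleSpectrum(s, cfg)), intensity(s))
})

test_that("default configuration yields 15000 points on [2000, 10000]", {
  cfg <- preprocessConfig()
  s <- MassSpectrum(seq(700, 12000, length.out = 3000),
                    rep(1, 3000))
  r <- resampleSpectrum(s, cfg)
  expect_length(mz(r), 15000)
  expect_equal(range(mz(r)), c(2000, 10000))
})

test_that("baseline correction removes constants and ramps, keeps peaks", {
  cfg <- preprocessConfig(gridN = 2000, baselineWindow = 400)
  grid <- seq(2000, 10000, length.out = 2000)

  # constant baseline -> all zero
  flat <- MassSpectrum(grid, rep(5, 2000))
  expect_equal(max(abs(intensity(correctBaseline(flat, cfg)))), 0)

  # isolated Gaussian peak on zero baseline: apex preserved within 5%
  peak <- 100 * exp(-((grid - 6000)^2) / (2 * 50^2))
  p <- correctBaseline(MassSpectrum(grid, peak), cfg)
  expect_gt(max(intensity(p)), 95)

  # peak on a linear ramp: off-peak residual < 10% of the ramp magnitude
  ramp <- seq(0, 200, length.out = 2000)
  pr <- correctBaseline(MassSpectrum(grid, peak + ramp), cfg)
  off <- abs(grid - 6000) > 500
  # exclude the edge windows where the running min is one-sided
  inner <- grid > 2500 & grid < 9500
  expect_lt(max(intensity(pr)[off & inner]), 20)

  expect_error(correctBaseline(flat, preprocessConfig(baselineWindow = 9000)),
               "span")
})

test_that("wavelet denoising passes smooth signals and suppresses noise", {
  cfg <- preprocessConfig(gridN = 3000)
  grid <- seq(2000, 10000, length.out = 3000)
  clean <- 100 * exp(-((grid - 5000)^2) / (2 * 80^2))

  # noiseless signal is essentially unchanged
  d0 <- denoiseSpectrum(MassSpectrum(grid, clean), cfg)
  expect_lt(max(abs(intensity(d0) - clean)) / max(clean), 1e-6)

  # all-zero spectrum stays zero
  z <- denoiseSpectrum(MassSpectrum(grid, rep(0, 3000)), cfg)
  expect_equal(intensity(z), rep(0, 3000))

  # white noise at 10% of apex: residual RMS reduced at least 2x, TIC ~kept
  set.seed(11)
  noisy <- clean + rnorm(3000, 0, 10)
  dn <- denoiseSpectrum(MassSpectrum(grid, noisy), cfg)
  rmsRaw <- sqrt(mean((noisy - clean)^2))
  rmsDen <- sqrt(mean((intensity(dn) - clean)^2))
  expect_gt(rmsRaw / rmsDen, 2)
  expect_lt(abs(sum(intensity(dn)) - sum(noisy)) / sum(noisy), 0.05)
})

test_that("moving-average denoising is available as an alternative", {
  cfg <- preprocessConfig(gridN = 500, denoiseMethod = "movavg",
                          denoiseLevel = 5)
  grid <- seq(2000, 10000, length.out = 500)
  set.seed(2)
  y <- 50 + rnorm(500, 0, 5)
  dn <- denoiseSpectrum(MassSpectrum(grid, y), cfg)
  expect_lt(sd(intensity(dn) - 50), sd(y - 50))
})

test_that("alignment moves a jittered peak onto the reference", {
  cfg <- preprocessConfig(gridN = 15000)
  grid <- seq(2000, 10000, length.out = 15000)
  step <- (10000 - 2000) / 14999
  # apex at 3885, reference 3883.321, within the 5 Da bound
  y <- 100 * exp(-((grid - 3885)^2) / (2 * 12^2)) +
       600 * exp(-((grid - (7766.159 + 3885 - 3883.321))^2) / (2 * 22^2))
  a <- alignSpectrum(MassSpectrum(grid, y), cfg)
  apex <- grid[which.max(intensity(a) * (abs(grid - 3883) < 30))]
  expect_lt(abs(apex - 3883.321), step + 1e-9)

  # an already aligned spectrum gets shift 0 and is unchanged
  y0 <- 100 * exp(-((grid - 3883.321)^2) / (2 * 12^2)) +
        600 * exp(-((grid - 7766.159)^2) / (2 * 22^2))
  a0 <- alignSpectrum(MassSpectrum(grid, y0), cfg)
  expect_equal(attr(a0, "shift"), 0)
  expect_equal(intensity(a0), y0)
})

test_that("alignment clamps at the shift bound with a warning", {
  cfg <- preprocessConfig(gridN = 4000, alignMaxShift = 5)
  grid <- seq(2000, 10000, length.out = 4000)
  step <- (10000 - 2000) / 3999
  y <- 100 * exp(-((grid - 3893.3)^2) / (2 * 12^2))  # needs ~10 Da
  expect_warning(a <- alignSpectrum(MassSpectrum(grid, y), cfg), "clamped")
  expect_lte(abs(attr(a, "shift")), 5 + step)

  badCfg <- preprocessConfig(alignReference = c(50))
  expect_error(alignSpectrum(MassSpectrum(grid, y), badCfg), "outside")
})

test_that("normalization obeys its definitions and scale invariance", {
  g <- c(2000, 3000)
  tic <- normalizeSpectrum(MassSpectrum(g, c(1, 3)),
                           preprocessConfig(normalization = "tic"))
  expect_equal(intensity(tic), c(0.25, 0.75))

  mx <- normalizeSpectrum(MassSpectrum(g, c(2, 8)),
                          preprocessConfig(normalization = "max"))
  expect_equal(intensity(mx), c(0.25, 1.0))

  cfg <- preprocessConfig(normalization = "tic")
  a <- normalizeSpectrum(MassSpectrum(g, c(2, 5)), cfg)
  b <- normalizeSpectrum(MassSpectrum(g, 7 * c(2, 5)), cfg)
  expect_equal(intensity(a), intensity(b))

  expect_error(normalizeSpectrum(MassSpectrum(g, c(0, 0)), cfg),
               "all-zero")
})

test_that("the pipeline returns a gridN-column set whatever the input size", {
  cfg <- makeTinyPreCfg(gridN = 800L)
  sim <- makeTinySimConfig(nCancer = 2L, nHealthy = 2L, rawN = 3000L)
  set <- preprocessSpectra(simulateSpectra(sim, seed = 4), cfg)
  expect_equal(dim(set), c(4L, 800L))
  expect_equal(classLabels(set), c(1L, 1L, 0L, 0L))

  # much denser raw input, same output dimension
  sim2 <- makeTinySimConfig(nCancer = 1L, nHealthy = 1L, rawN = 36000L)
  set2 <- preprocessSpectra(simulateSpectra(sim2, seed = 4), cfg)
  expect_equal(ncol(intensityMatrix(set2)), 800L)
})

test_that("pipeline with all optional stages disabled equals resample-only", {
  cfg <- preprocessConfig(gridN = 300, doBaseline = FALSE, doDenoise = FALSE,
                          doAlign = FALSE, normalization = "none")
  sim <- makeTinySimConfig(nCancer = 1L, nHealthy = 1L)
  sp <- simulateSpectra(sim, seed = 9)
  set <- preprocessSpectra(sp, cfg)
  manual <- do.call(rbind, lapply(sp, function(s)
    intensity(resampleSpectrum(s, cfg))))
  expect_equal(intensityMatrix(set), manual)
})

test_that("a jittered case/control pair is aligned onto the Fig-1 positions", {
  cfg <- preprocessConfig()
  sim <- simConfig(nCancer = 1L, nHealthy = 1L, noiseSd = 0, ampCv = 0,
                   jitterSd = 2)
  set <- preprocessSpectra(simulateSpectra(sim, seed = 31), cfg)
  grid <- mzGrid(set)
  step <- diff(grid[1:2])
  X <- intensityMatrix(set)
  for (i in 1:2) {
    for (p in c(3883.321, 7766.159)) {
      w <- which(abs(grid - p) < 60)
      apex <- grid[w[which.max(X[i, w])]]
      expect_lt(abs(apex - p), step + 1e-9)
    }
  }
})
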