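# Synthetic SELDI-TOF-like case/control spectra. The defaults emulate the
# characteristics of the public FDA-NCI ovarian serum cohort: 121 cancer and
# 95 healthy samples, a dense raw axis covering the informative band, two
# prominent peaks near m/z 3883.321 and 7766.159 whose apex intensities are
# class-dependent (healthy 126 / 719, cancer 130 / 608), per-spectrum m/z
# jitter (exercising alignment), a decaying-exponential chemical background,
# multiplicative amplitude variability and additive white noise.

#' Simulation configuration for synthetic case/control spectra
#'
#' @param nCancer,nHealthy sample counts per class.
#' @param rawN raw points per spectrum. The default (36000) keeps full test
#'   suites fast; 360000 reproduces full instrument resolution.
#' @param mzRange raw m/z axis range (Da), covering the informative band.
#' @param peaks data.frame of class-differential peaks with columns
#'   \code{position}, \code{width} (Gaussian sigma, Da), \code{ampHealthy},
#'   \code{ampCancer} (apex intensities).
#' @param sharedPeaks data.frame of class-invariant peaks with columns
#'   \code{position}, \code{amplitude}, \code{width}.
#' @param jitterSd per-spectrum rigid m/z shift standard deviation (Da).
#' @param baselineAmp,baselineDecay baseline model
#'   \code{baselineAmp * exp(-(mz - min(mz)) / baselineDecay)}.
#' @param noiseSd additive white-noise standard deviation.
#' @param ampCv per-spectrum, per-peak multiplicative lognormal amplitude
#'   coefficient of variation.
#' @param seed default RNG seed used by \code{\link{simulateSpectra}}.
#' @return a list of class \code{"msSimConfig"}.
#' @export
simConfig <- function(nCancer = 121L, nHealthy = 95L, rawN = 36000L,
                      mzRange = c(700, 12000),
                      peaks = data.frame(
                        position = c(3883.321, 7766.159, 4301.2, 9187.5),
                        width = c(12, 22, 16, 24),
                        ampHealthy = c(126, 719, 210, 90),
                        ampCancer = c(130, 608, 320, 145)),
                      sharedPeaks = data.frame(
                        position = c(2251.3, 4598.7, 5412.4, 6803.9, 8934.8),
                        amplitude = c(240, 160, 310, 130, 185),
                        width = c(9, 16, 18, 21, 26)),
                      jitterSd = 1.0, baselineAmp = 300,
                      baselineDecay = 2000, noiseSd = 10, ampCv = 0.1,
                      seed = 17L) {
  stopifnot(nCancer >= 1L, nHealthy >= 1L, rawN >= 2L,
            mzRange[1L] < mzRange[2L], jitterSd >= 0, noiseSd >= 0,
            ampCv >= 0, baselineDecay > 0,
            all(peaks$width > 0), all(sharedPeaks$width > 0),
            all(peaks$position > mzRange[1L]),
            all(peaks$position < mzRange[2L]),
            all(sharedPeaks$position > mzRange[1L]),
            all(sharedPeaks$position < mzRange[2L]))
  cfg <- list(nCancer = as.integer(nCancer), nHealthy = as.integer(nHealthy),
              rawN = as.integer(rawN), mzRange = as.numeric(mzRange),
              peaks = peaks, sharedPeaks = sharedPeaks,
              jitterSd = jitterSd, baselineAmp = baselineAmp,
              baselineDecay = baselineDecay, noiseSd = noiseSd,
              ampCv = ampCv, seed = as.integer(seed))
  class(cfg) <- "msSimConfig"
  cfg
}

# Add apex-scaled Gaussian peaks to y in place-ish; evaluation restricted to
# +/- 8 sigma around each position so the cost is independent of rawN.
.addPeaks <- function(y, mzAxis, positions, amplitudes, widths) {
  step <- (mzAxis[length(mzAxis)] - mzAxis[1L]) / (length(mzAxis) - 1L)
  for (k in seq_along(positions)) {
    p <- positions[k]; s <- widths[k]
    lo <- max(1L, floor((p - 8 * s - mzAxis[1L]) / step) + 1L)
    hi <- min(length(mzAxis), ceiling((p + 8 * s - mzAxis[1L]) / step) + 1L)
    if (lo > hi) next
    idx <- lo:hi
    y[idx] <- y[idx] + amplitudes[k] * exp(-((mzAxis[idx] - p)^2) / (2 * s^2))
  }
  y
}

#' Generate labeled synthetic raw spectra
#'
#' Each spectrum is a sum of Gaussian peaks (class-appropriate apex
#' amplitudes, each multiplied by an independent lognormal factor with
#' coefficient of variation \code{ampCv}; all positions rigidly shifted by a
#' per-spectrum Normal(0, \code{jitterSd}) offset), a decaying-exponential
#' baseline and additive Gaussian white noise, truncated at zero. Cancer
#' samples come first. Fully deterministic under \code{seed}.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param seed RNG seed; defaults to \code{cfg$seed}.
#' @return a list of labeled \linkS4class{MassSpectrum} objects of length
#'   \code{nCancer + nHealthy}.
#' @export
simulateSpectra <- function(cfg = simConfig(), seed = cfg$seed) {
  mzAxis <- seq(cfg$mzRange[1L], cfg$mzRange[2L], length.out = cfg$rawN)
  base <- cfg$baselineAmp * exp(-(mzAxis - cfg$mzRange[1L]) /
                                  cfg$baselineDecay)
  sdlog <- sqrt(log(1 + cfg$ampCv^2))
  nP <- nrow(cfg$peaks); nS <- nrow(cfg$sharedPeaks)
  labels <- c(rep(1L, cfg$nCancer), rep(0L, cfg$nHealthy))
  .withSeed(seed, {
    lapply(seq_along(labels), function(i) {
      lab <- labels[i]
      shift <- if (cfg$jitterSd > 0) stats::rnorm(1L, 0, cfg$jitterSd) else 0
      fac <- if (cfg$ampCv > 0)
        stats::rlnorm(nP + nS, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      else rep(1, nP + nS)
      amp <- if (lab == 1L) cfg$peaks$ampCancer else cfg$peaks$ampHealthy
      y <- .addPeaks(numeric(cfg$rawN), mzAxis,
                     cfg$peaks$position + shift, amp * fac[seq_len(nP)],
                     cfg$peaks$width)
      if (nS > 0L)
        y <- .addPeaks(y, mzAxis, cfg$sharedPeaks$position + shift,
                       cfg$sharedPeaks$amplitude * fac[nP + seq_len(nS)],
                       cfg$sharedPeaks$width)
      y <- y + base
      if (cfg$noiseSd > 0)
        y <- y + stats::rnorm(cfg$rawN, 0, cfg$noiseSd)
      MassSpectrum(mz = mzAxis, intensity = pmax(y, 0), label = lab,
                   sampleId = sprintf("%s%03d",
                                      if (lab == 1L) "C" else "H", i))
    })
  })
}

#' Sample directly from the PPCA generative model
#'
#' Draws \eqn{S = W X + \mu + \epsilon} with \eqn{X \sim N(0, I_q)} and
#' \eqn{\epsilon \sim N(0, \sigma^2 I_d)}. The loading matrix is itself a
#' seeded Gaussian draw scaled to \code{wNorm} per entry, fixed given the
#' seed, and returned together with the other true parameters so estimates
#' can be compared against the truth.
#'
#' @param n number of samples.
#' @param d observed dimension.
#' @param q latent dimension (< d).
#' @param wNorm standard deviation of the loading-matrix entries.
#' @param sigma2 isotropic noise variance.
#' @param mu mean vector (recycled to length d; default 0).
#' @param seed RNG seed.
#' @return a list with \code{S} (n-by-d matrix), \code{W}, \code{mu},
#'   \code{sigma2}.
#' @export
simulateLatentGaussian <- function(n, d, q, wNorm = 1, sigma2 = 1,
                                   mu = 0, seed = 1L) {
  stopifnot(q < d, n >= 1L, sigma2 >= 0)
  mu <- rep_len(as.numeric(mu), d)
  .withSeed(seed, {
    W <- matrix(stats::rnorm(d * q, sd = wNorm), d, q)
    X <- matrix(stats::rnorm(n * q), n, q)
    S <- X %*% t(W)
    if (sigma2 > 0)
      S <- S + matrix(stats::rnorm(n * d, sd = sqrt(sigma2)), n, d)
    S <- sweep(S, 2L, mu, "+")
    list(S = S, W = W, mu = mu, sigma2 = sigma2)
  })
}
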