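# Shared fixtures, built in code at test time.

# A tiny deterministic SpectrumSet with class-differential peaks, small
# enough that whole experiments finish in seconds.
makeTinySimConfig <- function(nCancer = 25L, nHealthy = 25L,
                              noiseSd = 10, ampCv = 0.1,
                              jitterSd = 1, rawN = 4000L) {
  simConfig(nCancer = nCancer, nHealthy = nHealthy, rawN = rawN,
            mzRange = c(1500, 10500), noiseSd = noiseSd, ampCv = ampCv,
            jitterSd = jitterSd)
}

makeTinyPreCfg <- function(gridN = 1500L) {
  preprocessConfig(gridN = gridN)
}

# Small fast SVM grid for tests where the full practitioner grid is overkill.
makeTinySvmCfg <- function(kFolds = 5L, seed = 1L) {
  svmConfig(cGrid = 2^c(-1, 3, 7), gGrid = 2^c(-9, -5, -1),
            kFolds = kFolds, seed = seed)
}

# Two seeded Gaussian blobs in 2-D, linearly separable when sep is large.
makeBlobs <- function(n = 40L, sep = 6, seed = 1L) {
  set.seed(seed)
  Z <- rbind(matrix(rnorm(n, 0, 1), n / 2L, 2L),
             matrix(rnorm(n, sep, 1), n / 2L, 2L))
  list(Z = Z, y = rep(c(0L, 1L), each = n / 2L))
}

writeTempLines <- function(lines, ext = ".csv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
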