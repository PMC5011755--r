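# End-to-end driver: simulate -> preprocess -> repeated hold-out evaluation,
# with a single master seed fanning out deterministically to stage seeds and
# a run manifest recording everything needed to regenerate the report.

#' Run the full pipeline end to end
#'
#' Simulates labeled raw spectra, preprocesses them onto the uniform grid,
#' and runs the repeated stratified hold-out comparison of PCA-SVM and
#' PPCA-SVM. The master seed fans out by fixed offsets: simulation uses
#' \code{seed}, the experiment driver uses \code{seed + 500000} (which in
#' turn derives split / EM-init / fold seeds by its own documented offsets),
#' so each stage is individually reproducible.
#'
#' @param simCfg a \code{\link{simConfig}}.
#' @param preCfg a \code{\link{preprocessConfig}}.
#' @param svmCfg an \code{\link{svmConfig}}.
#' @param methods methods to compare.
#' @param nRepeats hold-out repetitions.
#' @param q latent dimension policy (\code{"auto"} or integer).
#' @param cumvar cumulative-variance threshold for \code{q = "auto"}.
#' @param seed master seed.
#' @param ... further arguments passed to \code{\link{runExperiment}}.
#' @param verbose print stage progress.
#' @return a list with \code{report} (see \code{\link{runExperiment}}) and
#'   \code{manifest} (command, resolved configuration, seeds, package
#'   version, timestamp).
#' @export
runEndToEnd <- function(simCfg = simConfig(), preCfg = preprocessConfig(),
                        svmCfg = svmConfig(),
                        methods = c("pca-svm", "ppca-svm"),
                        nRepeats = 10L, q = "auto", cumvar = 0.9999,
                        seed = 17L, ..., verbose = FALSE) {
  seed <- as.integer(seed)
  if (verbose) message("simulating ", simCfg$nCancer + simCfg$nHealthy,
                       " spectra (", simCfg$rawN, " raw points) ...")
  spectra <- simulateSpectra(simCfg, seed = seed)
  if (verbose) message("preprocessing onto ", preCfg$gridN,
                       "-point grid ...")
  set <- preprocessSpectra(spectra, preCfg, verbose = verbose)
  if (verbose) message("running ", nRepeats, " hold-out repetitions ...")
  report <- runExperiment(set, methods = methods, nRepeats = nRepeats,
                          q = q, cumvar = cumvar, svmCfg = svmCfg,
                          seed = seed + 500000L, verbose = verbose, ...)
  manifest <- list(
    command = "runEndToEnd",
    config = list(sim = unclass(simCfg), preprocess = unclass(preCfg),
                  svm = unclass(svmCfg), methods = methods,
                  nRepeats = nRepeats, q = q, cumvar = cumvar),
    seeds = list(master = seed, simulate = seed,
                 experiment = seed + 500000L),
    version = as.character(utils::packageVersion("msppca")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  list(report = report, manifest = manifest)
}

#' Write a run manifest as JSON
#'
#' @param manifest the manifest of a \code{\link{runEndToEnd}} result.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeManifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
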