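# Spectrum, sample-sheet and matrix I/O. All on-disk formats are plain
# delimited text, the convention of the public SELDI serum datasets.

.sniffSep <- function(line) {
  if (grepl(",", line, fixed = TRUE)) return(",")
  if (grepl("\t", line, fixed = TRUE)) return("\t")
  ""
}

.splitFields <- function(lines, sep) {
  if (sep == "") strsplit(trimws(lines), "[[:space:]]+")
  else strsplit(lines, sep, fixed = TRUE)
}

.canonLabel <- function(tok) {
  t <- tolower(trimws(as.character(tok)))
  pos <- c("cancer", "positive", "1")
  neg <- c("healthy", "negative", "0")
  out <- rep(NA_integer_, length(t))
  out[t %in% pos] <- 1L
  out[t %in% neg] <- 0L
  unknown <- is.na(out) & !(t %in% c("", "na"))
  if (any(unknown))
    stop("unknown label token(s): ",
         paste(unique(t[unknown]), collapse = ", "),
         " (expected cancer/positive/1 or healthy/negative/0)")
  out
}

#' Read a spectrum from a two-column delimited text file
#'
#' Reads a (m/z, intensity) spectrum from plain text. The column separator
#' (comma, tab or whitespace) is sniffed from the first data line and a
#' single non-numeric header line is skipped automatically. Rows are sorted
#' by m/z; duplicated m/z points are averaged with a warning.
#'
#' @param path path to the spectrum file.
#' @param sep column separator; \code{"auto"} (default) sniffs it.
#' @param label optional class label to attach (0/1/NA).
#' @param sampleId sample identifier; defaults to the file name.
#' @return a \linkS4class{MassSpectrum}.
#' @export
readSpectrum <- function(path, sep = "auto", label = NA,
                         sampleId = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("malformed spectrum file (empty): ", path)
  if (identical(sep, "auto")) sep <- .sniffSep(lines[[1L]])
  fields <- .splitFields(lines, sep)
  first <- suppressWarnings(as.numeric(fields[[1L]]))
  skip <- anyNA(first)
  if (skip) fields <- fields[-1L]
  if (length(fields) < 2L)
    stop("malformed spectrum file: fewer than 2 data points in ", path)
  nums <- suppressWarnings(
    vapply(fields, function(f) as.numeric(f[1:2]), numeric(2)))
  bad <- which(colSums(is.na(nums)) > 0L)
  if (length(bad))
    stop("non-numeric spectrum row at line ", bad[1L] + as.integer(skip),
         " of ", path)
  m <- nums[1L, ]
  i <- nums[2L, ]
  ord <- order(m)
  m <- m[ord]; i <- i[ord]
  if (anyDuplicated(m)) {
    warning("duplicate m/z points in ", path, "; intensities averaged")
    i <- as.numeric(tapply(i, m, mean))
    m <- sort(unique(m))
  }
  MassSpectrum(mz = m, intensity = i, label = label, sampleId = sampleId)
}

#' Read a sample sheet
#'
#' A sample sheet is a delimited text file with a header and columns
#' \code{sample_id}, \code{path}, \code{label}. Label tokens
#' \code{cancer}/\code{positive}/\code{1} map to 1 and
#' \code{healthy}/\code{negative}/\code{0} map to 0, case-insensitively.
#' Relative paths are resolved against the sheet's directory.
#'
#' @param path path to the sheet.
#' @param checkFiles verify that every referenced spectrum file exists
#'   (default \code{TRUE}).
#' @return a \code{data.frame} with columns \code{sample_id}, \code{path},
#'   \code{label} (integer 0/1), in file order.
#' @export
readSampleSheet <- function(path, checkFiles = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("sample sheet needs a header and >= 1 row")
  sep <- .sniffSep(lines[[1L]])
  fields <- .splitFields(lines, sep)
  hdr <- tolower(trimws(fields[[1L]]))
  need <- c("sample_id", "path", "label")
  if (!all(need %in% hdr))
    stop("sample sheet must have columns sample_id, path, label")
  idx <- match(need, hdr)
  rows <- fields[-1L]
  get <- function(k) vapply(rows, function(f) trimws(f[idx[k]]), character(1))
  out <- data.frame(sample_id = get(1L), path = get(2L),
                    label = .canonLabel(get(3L)),
                    stringsAsFactors = FALSE)
  rel <- !file.exists(out$path)
  out$path[rel] <- file.path(dirname(path), out$path[rel])
  if (checkFiles) {
    miss <- !file.exists(out$path)
    if (any(miss))
      stop("sample sheet references missing file(s): ",
           paste(out$path[miss], collapse = ", "))
  }
  out
}

#' Stack spectra on an identical grid into a SpectrumSet
#'
#' All spectra must share a bitwise-identical m/z vector (as produced by
#' \code{\link{resampleSpectrum}} with one configuration); otherwise an error
#' instructs the caller to resample first.
#'
#' @param spectra list of \linkS4class{MassSpectrum} objects.
#' @return a \linkS4class{SpectrumSet}; labels and sample ids are carried
#'   through.
#' @export
assembleSpectrumSet <- function(spectra) {
  stopifnot(length(spectra) >= 1L)
  grid <- mz(spectra[[1L]])
  for (s in spectra)
    if (!identical(mz(s), grid))
      stop("spectra are not on a common m/z grid; resample them first")
  X <- do.call(rbind, lapply(spectra, intensity))
  ids <- vapply(spectra, function(s) s@sampleId, character(1))
  ids[is.na(ids)] <- paste0("S", which(is.na(ids)))
  SpectrumSet(X = X, grid = grid,
              labels = vapply(spectra, function(s) s@label, integer(1)),
              sampleIds = ids)
}

#' Write / read a SpectrumSet matrix file
#'
#' The matrix file is CSV with a header row \code{sample_id,label,<mz1>,...}
#' where the remaining header fields are the m/z grid printed with 15
#' significant digits; each following row holds one sample. The label field
#' is empty for unlabeled samples (the whole column may be absent, in which
#' case all labels read back as \code{NA}). Round-trips are exact to the
#' printed precision.
#'
#' @param set a \linkS4class{SpectrumSet}.
#' @param path output (input) file path.
#' @return \code{writeSpectrumMatrix} returns \code{path} invisibly;
#'   \code{readSpectrumMatrix} returns a \linkS4class{SpectrumSet}.
#' @export
writeSpectrumMatrix <- function(set, path) {
  stopifnot(is(set, "SpectrumSet"))
  fmt <- function(x) formatC(x, digits = 15, format = "g")
  hdr <- paste(c("sample_id", "label", fmt(set@grid)), collapse = ",")
  lab <- ifelse(is.na(set@labels), "", as.character(set@labels))
  rows <- vapply(seq_len(nrow(set@X)), function(n) {
    paste(c(set@sampleIds[n], lab[n], fmt(set@X[n, ])), collapse = ",")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname writeSpectrumMatrix
#' @export
readSpectrumMatrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("malformed matrix file: no sample rows")
  fields <- strsplit(lines, ",", fixed = TRUE)
  hdr <- fields[[1L]]
  hasLabel <- length(hdr) >= 2L && tolower(hdr[2L]) == "label"
  off <- if (hasLabel) 2L else 1L
  grid <- suppressWarnings(as.numeric(hdr[-seq_len(off)]))
  if (anyNA(grid)) stop("malformed matrix header: non-numeric m/z fields")
  d <- length(grid)
  rows <- fields[-1L]
  n <- length(rows)
  X <- matrix(0, n, d)
  labels <- rep(NA_integer_, n)
  ids <- character(n)
  for (r in seq_len(n)) {
    f <- rows[[r]]
    if (length(f) != d + off)
      stop("ragged matrix row ", r, ": expected ", d + off, " fields, got ",
           length(f))
    ids[r] <- f[1L]
    if (hasLabel && nzchar(f[2L])) labels[r] <- as.integer(f[2L])
    v <- suppressWarnings(as.numeric(f[-seq_len(off)]))
    if (anyNA(v)) stop("non-numeric intensity in matrix row ", r)
    X[r, ] <- v
  }
  SpectrumSet(X = X, grid = grid, labels = labels, sampleIds = ids)
}

#' Write spectra and a sample sheet to a directory
#'
#' Writes one two-column CSV per spectrum plus a tab-separated sample sheet
#' consumable by \code{\link{readSampleSheet}}.
#'
#' @param spectra list of \linkS4class{MassSpectrum} objects.
#' @param dir output directory (created if needed).
#' @param sheet sample sheet file name within \code{dir}.
#' @return the sheet path, invisibly.
#' @export
writeSpectra <- function(spectra, dir, sheet = "samples.tsv") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- character(length(spectra))
  files <- character(length(spectra))
  labs <- character(length(spectra))
  for (k in seq_along(spectra)) {
    s <- spectra[[k]]
    ids[k] <- if (is.na(s@sampleId)) sprintf("S%03d", k) else s@sampleId
    files[k] <- paste0(ids[k], ".csv")
    labs[k] <- if (is.na(s@label)) "" else
      c("healthy", "cancer")[s@label + 1L]
    writeLines(c("mz,intensity",
                 paste(formatC(s@mz, digits = 15, format = "g"),
                       formatC(s@intensity, digits = 15, format = "g"),
                       sep = ",")),
               file.path(dir, files[k]))
  }
  sheetPath <- file.path(dir, sheet)
  writeLines(c("sample_id\tpath\tlabel",
               paste(ids, files, labs, sep = "\t")), sheetPath)
  invisible(sheetPath)
}
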