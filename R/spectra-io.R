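#' @include AllClasses.R
NULL

# ---- matrix dialect -------------------------------------------------------
# Self-describing container used for exact round trips: a short text header
# (magic line, key: value pairs, DATA sentinel) followed by the intensities
# as raw little-endian float64 in row-major order. Axis values are printed
# with 17 significant digits, so header fields round-trip bit-exactly.

MATRIX_MAGIC <- "SIAPCA-MATRIX 1"

.num17 <- function(x) formatC(x, digits = 17, format = "g")

.writeMatrixDialect <- function(spectrum, path) {
  m <- spectrum@intensities
  hdr <- c(
    MATRIX_MAGIC,
    paste0("n1: ", nrow(m)),
    paste0("n2: ", ncol(m)),
    paste0("sw_h: ", .num17(spectrum@axisH$sw)),
    paste0("first_h: ", .num17(spectrum@axisH$first)),
    paste0("obs_h: ", .num17(spectrum@axisH$obs)),
    paste0("sw_n: ", .num17(spectrum@axisN$sw)),
    paste0("first_n: ", .num17(spectrum@axisN$first)),
    paste0("obs_n: ", .num17(spectrum@axisN$obs)),
    paste0("label: ", spectrum@label),
    "DATA")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  writeBin(as.vector(t(m)), con, size = 8L, endian = "little")
  invisible(NULL)
}

.readMatrixDialect <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  sentinel <- charToRaw("\nDATA\n")
  pos <- NA_integer_
  limit <- min(length(raw), 4096L)
  for (i in seq_len(limit - length(sentinel) + 1L)) {
    if (raw[i] == sentinel[1L] &&
        identical(raw[i:(i + length(sentinel) - 1L)], sentinel)) {
      pos <- i
      break
    }
  }
  if (is.na(pos)) stop("matrix dialect: missing DATA sentinel in ", path)
  hdr <- strsplit(rawToChar(raw[seq_len(pos - 1L)]), "\n", fixed = TRUE)[[1]]
  if (!identical(hdr[1], MATRIX_MAGIC))
    stop("matrix dialect: bad magic line '", hdr[1], "' in ", path)
  kv <- hdr[-1]
  keys <- sub(":.*$", "", kv)
  vals <- sub("^[^:]*: ?", "", kv)
  names(vals) <- keys
  need <- c("n1", "n2", "sw_h", "first_h", "obs_h", "sw_n", "first_n", "obs_n")
  missing <- setdiff(need, keys)
  if (length(missing))
    stop("matrix dialect: missing header field '", missing[1], "' in ", path)
  n1 <- as.integer(vals[["n1"]]); n2 <- as.integer(vals[["n2"]])
  dataRaw <- raw[(pos + length(sentinel)):length(raw)]
  nVals <- length(dataRaw) %/% 8L
  if (nVals != n1 * n2)
    stop(sprintf("matrix dialect: expected %d x %d = %d values, file holds %d",
                 n1, n2, n1 * n2, nVals))
  v <- readBin(dataRaw, "numeric", n = nVals, size = 8L, endian = "little")
  Spectrum2D(matrix(v, nrow = n1, ncol = n2, byrow = TRUE),
             nmrAxis(n1, as.numeric(vals[["sw_h"]]),
                     as.numeric(vals[["first_h"]]), as.numeric(vals[["obs_h"]])),
             nmrAxis(n2, as.numeric(vals[["sw_n"]]),
                     as.numeric(vals[["first_n"]]), as.numeric(vals[["obs_n"]])),
             if ("label" %in% keys) vals[["label"]] else "")
}

# ---- NMRPipe 2D -----------------------------------------------------------
# Standard 512-float32 header followed by float32 intensities, one direct-
# dimension (F2 = 1H) trace per indirect (F1 = 15N) increment. Only single
# real 2D planes are supported; pseudo-3D files must be split upstream.
# Header indices below are the standard 0-based FDATA positions.

FD <- list(MAGIC = 0L, FLTFORMAT = 1L, FLTORDER = 2L, DIMCOUNT = 9L,
           F1QUADFLAG = 55L, F2QUADFLAG = 56L, SIZE = 99L, F2SW = 100L,
           F2ORIG = 101L, QUADFLAG = 106L, F2OBS = 119L, F1OBS = 218L,
           SPECNUM = 219L, F2FTFLAG = 220L, TRANSPOSED = 221L,
           F1FTFLAG = 222L, F1SW = 229L, F1ORIG = 249L, PHASE2D = 256L,
           FILECOUNT = 442L)

.fltFormatValue <- function() {
  # float32 whose bit pattern is 0xeeeeeeee, the standard format magic
  readBin(packBits(intToBits(-286331154L)), "numeric", size = 4L,
          endian = "little")
}

# ORIG is the Hz frequency of the last point: ppm_i = (orig + sw*(n-1-i)/n)/obs
.origHz <- function(axis) {
  axis$obs * (axis$first - (axis$n - 1L) * axis$sw / axis$n)
}

.writeNmrPipe2D <- function(spectrum, path) {
  m <- spectrum@intensities
  h <- numeric(512L)
  put <- function(idx, val) h[idx + 1L] <<- val
  put(FD$MAGIC, 0)
  put(FD$FLTFORMAT, .fltFormatValue())
  put(FD$FLTORDER, 2.345)
  put(FD$DIMCOUNT, 2)
  put(FD$F2QUADFLAG, 1); put(FD$F1QUADFLAG, 1); put(FD$QUADFLAG, 1)
  put(FD$F2FTFLAG, 1); put(FD$F1FTFLAG, 1)
  put(FD$TRANSPOSED, 0); put(FD$PHASE2D, 2); put(FD$FILECOUNT, 1)
  put(FD$SIZE, nrow(m))          # points per F2 (direct, 1H) trace
  put(FD$SPECNUM, ncol(m))       # number of F1 (indirect, 15N) increments
  put(FD$F2SW, spectrum@axisH$sw * spectrum@axisH$obs)
  put(FD$F2OBS, spectrum@axisH$obs)
  put(FD$F2ORIG, .origHz(spectrum@axisH))
  put(FD$F1SW, spectrum@axisN$sw * spectrum@axisN$obs)
  put(FD$F1OBS, spectrum@axisN$obs)
  put(FD$F1ORIG, .origHz(spectrum@axisN))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(h, con, size = 4L, endian = "little")
  writeBin(as.vector(m), con, size = 4L, endian = "little")
  invisible(NULL)
}

.readNmrPipe2D <- function(path) {
  sz <- file.size(path)
  if (is.na(sz) || sz < 512L * 4L)
    stop("not an NMRPipe file (shorter than the 512-float header): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- readBin(con, "numeric", n = 512L, size = 4L, endian = "little")
  get <- function(idx) h[idx + 1L]
  if (get(FD$MAGIC) != 0)
    stop("not an NMRPipe file (header field FDMAGIC is nonzero): ", path)
  if (abs(get(FD$FLTORDER) - 2.345) > 1e-4)
    stop("unsupported NMRPipe byte order (FDFLTORDER != 2.345): ", path)
  dimCount <- get(FD$DIMCOUNT)
  if (dimCount != 2)
    stop(sprintf("expected 2D data but FDDIMCOUNT is %g: %s", dimCount, path))
  if (get(FD$QUADFLAG) != 1 || get(FD$F2QUADFLAG) != 1 ||
      get(FD$F1QUADFLAG) != 1)
    stop("only real (singular quadrature) 2D data are supported: ", path)
  n1 <- as.integer(get(FD$SIZE))
  n2 <- as.integer(get(FD$SPECNUM))
  if (n1 < 2L || n2 < 2L)
    stop(sprintf("bad point counts in header (FDSIZE %d, FDSPECNUM %d): %s",
                 n1, n2, path))
  nAvail <- (sz - 512L * 4L) %/% 4L
  if (nAvail != n1 * n2) {
    if (nAvail %% (n1 * n2) == 0L && nAvail > n1 * n2)
      stop(sprintf("pseudo-3D input: file holds %d planes of %d x %d; split planes upstream",
                   nAvail %/% (n1 * n2), n1, n2))
    stop(sprintf("data size mismatch: header implies %d points, file holds %d",
                 n1 * n2, nAvail))
  }
  v <- readBin(con, "numeric", n = n1 * n2, size = 4L, endian = "little")
  axisFrom <- function(swHz, obs, orig, n) {
    swPpm <- swHz / obs
    nmrAxis(n, swPpm, orig / obs + (n - 1L) * swPpm / n, obs)
  }
  Spectrum2D(matrix(v, nrow = n1, ncol = n2),
             axisFrom(get(FD$F2SW), get(FD$F2OBS), get(FD$F2ORIG), n1),
             axisFrom(get(FD$F1SW), get(FD$F1OBS), get(FD$F1ORIG), n2),
             "")
}

#' Read a 2D spectrum
#'
#' Reads a processed frequency-domain 2D spectrum from either the package's
#' plain matrix dialect (exact float64 round trip) or NMRPipe 2D format
#' (single real plane, 512-float header, float32 data).
#'
#' @param path file path.
#' @param format \code{"matrix"} or \code{"nmrpipe2d"}.
#' @return a [Spectrum2D-class].
#' @examples
#' s <- Spectrum2D(matrix(rnorm(12), 4, 3),
#'                 nmrAxis(4, 2, 10), nmrAxis(3, 10, 130), "free")
#' f <- tempfile()
#' writeSpectrum(s, f, "matrix")
#' identical(intensities(readSpectrum(f, "matrix")), intensities(s))
#' @export
readSpectrum <- function(path, format = c("matrix", "nmrpipe2d")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         matrix = .readMatrixDialect(path),
         nmrpipe2d = .readNmrPipe2D(path))
}

#' Write a 2D spectrum
#'
#' The matrix dialect round-trips bit-exactly; NMRPipe stores float32, so
#' intensities and calibration round-trip within single-precision rounding.
#' The spectrum is validated before any file is produced.
#'
#' @param spectrum a [Spectrum2D-class].
#' @inheritParams readSpectrum
#' @export
writeSpectrum <- function(spectrum, path, format = c("matrix", "nmrpipe2d")) {
  format <- match.arg(format)
  validObject(spectrum)
  switch(format,
         matrix = .writeMatrixDialect(spectrum, path),
         nmrpipe2d = .writeNmrPipe2D(spectrum, path))
  invisible(NULL)
}

# ---- peak lists -----------------------------------------------------------

#' Construct a peak list
#'
#' A peak list is a data.frame with columns \code{id} (unique assignment
#' identifier), \code{h_ppm}, \code{n_ppm} and \code{intensity}.
#'
#' @param id character vector of assignment ids, unique.
#' @param h_ppm,n_ppm peak coordinates in ppm.
#' @param intensity peak heights (arbitrary units).
#' @return a validated peak-list data.frame.
#' @export
peakList <- function(id, h_ppm, n_ppm, intensity = 1) {
  df <- data.frame(id = as.character(id), h_ppm = as.numeric(h_ppm),
                   n_ppm = as.numeric(n_ppm),
                   intensity = as.numeric(rep_len(intensity, length(id))),
                   stringsAsFactors = FALSE)
  .validatePeakList(df)
  df
}

.validatePeakList <- function(df) {
  need <- c("id", "h_ppm", "n_ppm", "intensity")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("peak list missing column '", missing[1], "'")
  dup <- df$id[duplicated(df$id)]
  if (length(dup))
    stop("duplicate assignment id '", dup[1], "' in peak list")
  if (any(!is.finite(df$h_ppm)) || any(!is.finite(df$n_ppm)))
    stop("peak coordinates must be finite")
  invisible(df)
}

#' Read / write a peak list
#'
#' Peak lists are comma- or tab-separated tables with a header line naming
#' \code{id, h_ppm, n_ppm, intensity}; the separator is detected from the
#' header. Writing uses CSV with coordinates at full precision.
#'
#' @param path file path.
#' @return \code{readPeakList}: a peak-list data.frame in file order.
#' @export
readPeakList <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          colClasses = NA, strip.white = TRUE)
  df$id <- as.character(df$id)
  .validatePeakList(df)
  df[, c("id", "h_ppm", "n_ppm", "intensity")]
}

#' @rdname readPeakList
#' @param peaks a peak-list data.frame (see [peakList()]).
#' @export
writePeakList <- function(peaks, path) {
  .validatePeakList(peaks)
  utils::write.csv(peaks[, c("id", "h_ppm", "n_ppm", "intensity")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

# ---- pool labels and ensembles --------------------------------------------

#' Display name of an RNA pool
#'
#' A pool fixes one base at the scanned position and randomizes the rest:
#' position 4, base A, length 5 gives \code{"NNNAN"}.
#'
#' @param position scanned position, 1..length.
#' @param base one of \code{A, C, G, U}.
#' @param length RNA length (default 5).
#' @return the pool name string.
#' @examples
#' poolLabelName(4, "A")  # "NNNAN"
#' @export
poolLabelName <- function(position, base, length = 5L) {
  position <- as.integer(position)
  base <- match.arg(base, BASES)
  if (position < 1L || position > length)
    stop("position must lie in 1..", length)
  chars <- rep("N", length)
  chars[position] <- base
  paste(chars, collapse = "")
}

#' Stack one position's spectra into a PCA-ready ensemble
#'
#' Assembles the free-protein reference and the four pool-bound spectra of
#' one scanned position into an [EnsembleStack-class], the pseudo-3D unit
#' the PCA consumes. All five spectra must share grid dimensions and axis
#' calibration (spectral widths and first-point ppm within 1e-6 ppm).
#'
#' @param reference the free-protein [Spectrum2D-class].
#' @param boundByBase named list (names \code{A, C, G, U}) of bound spectra.
#' @param position scanned RNA position (integer).
#' @return a validated [EnsembleStack-class] with plane order
#'   \code{[free, A, C, G, U]}.
#' @export
stackEnsemble <- function(reference, boundByBase, position) {
  missing <- setdiff(BASES, names(boundByBase))
  if (length(missing))
    stop("missing bound spectrum for base '", missing[1], "'")
  new("EnsembleStack", reference = reference,
      bound = boundByBase[BASES], position = as.integer(position))
}
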