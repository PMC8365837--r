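# Region-mean extraction, confound regression and band-pass filtering.

#' Construct a RegionTimeseries
#'
#' @param data numeric matrix, volumes x regions.
#' @param tr repetition time in seconds.
#' @param regionLabels region names; defaults to `colnames(data)`.
#' @param subjectId subject identifier.
#' @return a [RegionTimeseries-class].
#' @export
regionTimeseries <- function(data, tr, regionLabels = colnames(data),
                             subjectId = "subject") {
  data <- as.matrix(data)
  if (!is.null(regionLabels)) colnames(data) <- regionLabels
  new("RegionTimeseries", data = data, tr = as.numeric(tr),
      subjectId = as.character(subjectId))
}

#' Extract region-mean timeseries from a labelled 4-D volume
#'
#' Averages the BOLD signal over the voxels of each labelled region, volume
#' by volume. Region order follows the label map.
#'
#' @param bold 4-D numeric array (x, y, z, t) or path to a NIfTI file.
#' @param labels 3-D integer array of region ids (same spatial grid) or path
#'   to a NIfTI file.
#' @param labelMap data.frame with columns `id` and `name`, or path to a
#'   two-column TSV.
#' @param tr repetition time in seconds (taken from the NIfTI header when
#'   `bold` is a file path and `tr` is missing).
#' @param subjectId subject identifier.
#' @return a [RegionTimeseries-class] with one column per mapped region.
#' @export
extractRegionMeans <- function(bold, labels, labelMap, tr = NULL,
                               subjectId = "subject") {
  if (is.character(bold)) {
    img <- RNifti::readNifti(bold)
    if (is.null(tr)) tr <- RNifti::pixdim(img)[4]
    bold <- as.array(img)
  }
  if (is.character(labels)) labels <- as.array(RNifti::readNifti(labels))
  if (is.character(labelMap)) labelMap <- readLabelMap(labelMap)
  stopifnot(is.data.frame(labelMap), all(c("id", "name") %in% names(labelMap)))
  if (is.null(tr)) stop("tr must be supplied when bold is an array")
  if (length(dim(bold)) != 4L) stop("bold must be a 4-D array")
  if (length(dim(labels)) != 3L) stop("labels must be a 3-D array")
  if (!all(dim(bold)[1:3] == dim(labels)))
    stop("spatial dimensions of bold and labels disagree")

  nT <- dim(bold)[4]
  flat <- matrix(bold, nrow = prod(dim(labels)), ncol = nT)
  lab <- as.integer(labels)
  out <- vapply(seq_len(nrow(labelMap)), function(r) {
    idx <- which(lab == labelMap$id[r])
    if (!length(idx))
      stop(sprintf("region '%s' (id %d) has no voxels in the label volume",
                   labelMap$name[r], as.integer(labelMap$id[r])))
    colMeans(flat[idx, , drop = FALSE])
  }, numeric(nT))
  colnames(out) <- labelMap$name
  regionTimeseries(out, tr = tr, subjectId = subjectId)
}

#' Read a two-column region label map (id, name)
#' @param path TSV path with header columns `id`, `name`.
#' @return data.frame with columns `id`, `name`.
#' @export
readLabelMap <- function(path) {
  lm <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "name") %in% names(lm)))
  lm
}

#' Regress nuisance confounds from region timeseries
#'
#' Ordinary-least-squares projection of each region series onto the
#' orthogonal complement of `[intercept | confounds]`. The intercept is
#' always included, so residuals have zero temporal mean. Rank-deficient
#' confound sets are reduced to an independent column subset with a warning.
#'
#' @param ts a [RegionTimeseries-class].
#' @param confounds numeric matrix with `nVolumes(ts)` rows (e.g. motion
#'   plus data-driven noise regressors), or NULL for intercept-only.
#' @return a [RegionTimeseries-class] of residuals.
#' @export
regressConfounds <- function(ts, confounds = NULL) {
  Y <- ts@data
  if (is.null(confounds) || NCOL(confounds) == 0L) {
    res <- sweep(Y, 2L, colMeans(Y))
    return(regionTimeseries(res, ts@tr, subjectId = ts@subjectId))
  }
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != nrow(Y))
    stop("confound matrix must have one row per volume")
  X <- cbind(1, confounds)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- qx$pivot[seq(qx$rank + 1L, ncol(X))]
    nm <- colnames(confounds)
    if (is.null(nm)) nm <- paste0("confound", seq_len(ncol(confounds)))
    warning("dropping linearly dependent confound column(s): ",
            paste(c("(intercept)", nm)[dropped], collapse = ", "))
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(X)
  }
  res <- qr.resid(qx, Y)
  dimnames(res) <- dimnames(Y)
  regionTimeseries(res, ts@tr, subjectId = ts@subjectId)
}

## ---- zero-phase band-pass filtering -------------------------------------

# steady-state initial conditions of the direct-form-II-transposed filter
# (unit step response state), so forward/backward passes start transient-free
.lfilterZi <- function(b, a) {
  n <- max(length(a), length(b))
  a <- c(a, numeric(n - length(a)))
  b <- c(b, numeric(n - length(b)))
  b <- b / a[1]; a <- a / a[1]
  comp <- rbind(-a[-1], cbind(diag(1, n - 2L), numeric(n - 2L)))
  IminusA <- diag(1, n - 1L) - t(comp)
  B <- b[-1] - a[-1] * b[1]
  solve(IminusA, B)
}

# direct-form-II-transposed IIR filter applied down the rows of a matrix,
# vectorized across columns; z0 is the initial state (nstate x ncol)
.lfilterMat <- function(b, a, x, z0 = NULL) {
  n <- max(length(a), length(b))
  a <- c(a, numeric(n - length(a)))
  b <- c(b, numeric(n - length(b)))
  b <- b / a[1]; a <- a / a[1]
  nr <- nrow(x); nc <- ncol(x)
  y <- matrix(0, nr, nc)
  z <- if (is.null(z0)) matrix(0, n - 1L, nc) else z0
  for (t in seq_len(nr)) {
    xt <- x[t, ]
    yt <- b[1] * xt + z[1L, ]
    for (i in seq_len(n - 2L))
      z[i, ] <- z[i + 1L, ] + b[i + 1L] * xt - a[i + 1L] * yt
    z[n - 1L, ] <- b[n] * xt - a[n] * yt
    y[t, ] <- yt
  }
  y
}

# zero-phase forward-backward filtering with odd-reflection padding and
# steady-state initial conditions (matrix columns filtered independently)
.filtfiltMat <- function(b, a, x) {
  n <- max(length(a), length(b))
  nr <- nrow(x)
  pad <- min(nr - 1L, 3L * (n - 1L))
  if (pad < 1L) stop("series too short to filter")
  top <- 2 * matrix(x[1L, ], pad, ncol(x), byrow = TRUE) -
    x[seq(pad + 1L, 2L), , drop = FALSE]
  bot <- 2 * matrix(x[nr, ], pad, ncol(x), byrow = TRUE) -
    x[seq(nr - 1L, nr - pad), , drop = FALSE]
  ext <- rbind(top, x, bot)
  zi <- .lfilterZi(b, a)
  y <- .lfilterMat(b, a, ext, outer(zi, ext[1L, ]))
  y <- y[rev(seq_len(nrow(y))), , drop = FALSE]
  y <- .lfilterMat(b, a, y, outer(zi, y[1L, ]))
  y <- y[rev(seq_len(nrow(y))), , drop = FALSE]
  y[seq(pad + 1L, pad + nr), , drop = FALSE]
}

# the zero-phase Butterworth is a fixed linear operator for given (T, band);
# materialize it once and reuse, so filtering a cohort is a single matmul
.filterCache <- new.env(parent = emptyenv())

.butterOperator <- function(nT, low, high, fs, order) {
  key <- paste(nT, low, high, fs, order, sep = "|")
  F <- .filterCache[[key]]
  if (is.null(F)) {
    bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
    F <- .filtfiltMat(bf$b, bf$a, diag(nT))
    .filterCache[[key]] <- F
  }
  F
}

.fftBandpassMat <- function(x, low, high, fs) {
  nr <- nrow(x)
  f <- (seq_len(nr) - 1) / nr * fs
  f <- pmin(f, fs - f)  # two-sided frequency axis
  keep <- f >= low - 1e-12 & f <= high + 1e-12
  X <- stats::mvfft(x)
  X[!keep, ] <- 0
  Re(stats::mvfft(X, inverse = TRUE)) / nr
}

#' Band-pass filter region timeseries
#'
#' Zero-phase filtering of every region series to the `[low, high]` band
#' (default 0.04-0.07 Hz). The default implementation is a forward-backward
#' (zero phase) Butterworth of order 5; an ideal FFT band filter is
#' available as an alternative. Output length equals input length.
#'
#' @param ts a [RegionTimeseries-class].
#' @param low,high band edges in Hz; must satisfy
#'   `0 < low < high < 1/(2*tr)`.
#' @param method "butterworth" (default) or "fft".
#' @param order Butterworth order (default 5).
#' @return a filtered [RegionTimeseries-class].
#' @export
bandpass <- function(ts, low = 0.04, high = 0.07,
                     method = c("butterworth", "fft"), order = 5) {
  method <- match.arg(method)
  fs <- 1 / ts@tr
  if (!(low > 0 && high > low && high < fs / 2))
    stop(sprintf("band must satisfy 0 < low < high < Nyquist = %.4g Hz",
                 fs / 2))
  Y <- ts@data
  out <- switch(method,
    butterworth = .butterOperator(nrow(Y), low, high, fs, order) %*% Y,
    fft = .fftBandpassMat(Y, low, high, fs))
  dimnames(out) <- dimnames(Y)
  regionTimeseries(out, ts@tr, subjectId = ts@subjectId)
}

## ---- timeseries I/O ------------------------------------------------------

#' Write region timeseries as TSV plus JSON sidecar
#'
#' One row per volume, one column per region, header = region labels; the
#' sidecar (same path with .json extension) records `tr` and `subject_id`.
#'
#' @param ts a [RegionTimeseries-class].
#' @param path output TSV path.
#' @export
writeRegionTimeseries <- function(ts, path) {
  df <- as.data.frame(signif(ts@data, 10))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- sub("\\.tsv$", ".json", path)
  if (identical(side, path)) side <- paste0(path, ".json")
  jsonlite::write_json(list(tr = ts@tr, subject_id = ts@subjectId),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read region timeseries written by [writeRegionTimeseries()]
#' @param path TSV path (sidecar JSON expected alongside).
#' @return a [RegionTimeseries-class].
#' @export
readRegionTimeseries <- function(path) {
  d <- as.matrix(utils::read.delim(path, check.names = FALSE))
  side <- sub("\\.tsv$", ".json", path)
  if (identical(side, path)) side <- paste0(path, ".json")
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  regionTimeseries(d, tr = meta$tr, subjectId = meta$subject_id)
}
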