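# Removal of modelled IED influence by orthogonal projection.

#' Build the IED design matrix
#'
#' Concatenates [buildEventRegressors()] output across spike types (three
#' columns per type: canonical, temporal derivative, dispersion derivative)
#' and mean-centers every column. The numerical rank of the centered design
#' is attached as attribute `"rank"` and reported when deficient (e.g. for
#' duplicated trains).
#'
#' @param eventTrains list of [EventTrain-class] objects, one per spike
#'   type (a single train is accepted).
#' @param basis an [HRFBasis-class].
#' @param nVolumes number of acquired volumes.
#' @param tr repetition time in seconds.
#' @return a [DesignMatrix-class] with `3 * length(eventTrains)` columns.
#' @export
buildIEDDesign <- function(eventTrains, basis, nVolumes, tr) {
  if (is(eventTrains, "EventTrain")) eventTrains <- list(eventTrains)
  if (!length(eventTrains) || !sum(vapply(eventTrains, length, 1L)))
    stop("no IED events supplied: skip the IED correction for this subject")
  dm <- buildEventRegressors(eventTrains, basis, nVolumes, tr)
  X <- sweep(dm@data, 2L, colMeans(dm@data))
  r <- qr(X)$rank
  if (r < ncol(X))
    message(sprintf("IED design is rank deficient: rank %d < %d columns",
                    r, ncol(X)))
  attr(X, "rank") <- r
  new("DesignMatrix", data = X, tr = dm@tr)
}

#' Project region timeseries onto the orthogonal complement of the IED design
#'
#' Returns `ts - X pinv(X) ts` with `X = [intercept | design]`: the residual
#' of every region series after least-squares removal of the modelled IED
#' response. Residuals are orthogonal to every design column; the projection
#' is idempotent. Rank-deficient designs are handled by the pivoted QR
#' (equivalent to the pseudoinverse solution) with the rank reported.
#'
#' @param ts a [RegionTimeseries-class].
#' @param design a [DesignMatrix-class] with `nVolumes(ts)` rows.
#' @return the IED-corrected [RegionTimeseries-class].
#' @export
projectOutIEDs <- function(ts, design) {
  X <- cbind(1, design@data)
  if (nrow(X) != nrow(ts@data))
    stop("design matrix and timeseries row counts disagree")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    message(sprintf("projecting with rank-deficient design (rank %d of %d)",
                    qx$rank, ncol(X)))
    # an independent column subset spans the same space as the pseudoinverse
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(X)
  }
  res <- qr.resid(qx, ts@data)
  dimnames(res) <- dimnames(ts@data)
  regionTimeseries(res, ts@tr, subjectId = ts@subjectId)
}

#' Export a design matrix as TSV with named columns
#' @param design a [DesignMatrix-class].
#' @param path output path.
#' @export
writeDesignMatrix <- function(design, path) {
  write.table(as.data.frame(design@data), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
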