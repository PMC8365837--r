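# Correlation adjacency, proportional-density thresholding, centrality
# curves and their area under the curve.

#' Pearson-correlation adjacency matrix
#'
#' Correlates every pair of region series, sets the diagonal
#' (self-correlation) to 0 and re-assigns all negative correlations to 0.
#'
#' @param ts a [RegionTimeseries-class] with at least 3 volumes.
#' @return symmetric R x R numeric matrix with entries in \[0, 1\] and zero
#'   diagonal; dimnames are the region labels.
#' @export
correlationAdjacency <- function(ts) {
  Y <- ts@data
  if (nrow(Y) < 3L) stop("need at least 3 volumes to correlate")
  Z <- Y - rep(colMeans(Y), each = nrow(Y))
  S <- crossprod(Z)
  s <- sqrt(diag(S))
  if (any(s == 0))
    stop("zero-variance region series: ",
         paste(colnames(Y)[s == 0], collapse = ", "))
  A <- S / tcrossprod(s)
  A <- (A + t(A)) / 2  # exact symmetry
  dimnames(A) <- list(colnames(Y), colnames(Y))
  diag(A) <- 0
  A[A < 0] <- 0
  A
}

# upper-triangle edge list ordered by decreasing weight, ties broken
# lexicographically on (i, j); only positive-weight edges are returned
.sortedEdges <- function(adj) {
  R <- nrow(adj)
  idx <- which(upper.tri(adj))
  w <- adj[idx]
  i <- ((idx - 1L) %% R) + 1L
  j <- ((idx - 1L) %/% R) + 1L
  o <- order(-w, i, j)
  keep <- w[o] > 0
  list(i = i[o][keep], j = j[o][keep], w = w[o][keep],
       nPossible = R * (R - 1L) / 2L)
}

#' Threshold an adjacency matrix at a proportional network density
#'
#' Retains the `floor(density * R*(R-1)/2)` largest-weight edges among the
#' upper-triangle entries, sets them to 1 and everything else to 0, then
#' symmetrizes. Zero-weight (absent) edges are never retained, so past the
#' point where all positive correlations are in the graph the edge count
#' stops growing. Ties at the boundary are broken deterministically in
#' lexicographic (i, j) order.
#'
#' @param adj symmetric non-negative weight matrix with zero diagonal.
#' @param density proportion of all possible edges to retain, in (0, 1].
#' @return binary symmetric matrix of the same dimension.
#' @export
thresholdAtDensity <- function(adj, density) {
  if (!(density > 0 && density <= 1)) stop("density must lie in (0, 1]")
  ed <- .sortedEdges(adj)
  k <- min(floor(density * ed$nPossible + 1e-9), length(ed$w))
  B <- matrix(0, nrow(adj), ncol(adj), dimnames = dimnames(adj))
  if (k > 0L) {
    sel <- seq_len(k)
    B[cbind(ed$i[sel], ed$j[sel])] <- 1
    B[cbind(ed$j[sel], ed$i[sel])] <- 1
  }
  B
}

#' Degree centrality of a binary graph
#'
#' Number of links connected to each node: the row sums of the binarized
#' adjacency matrix.
#'
#' @param binaryAdj binary symmetric adjacency matrix.
#' @return integer-valued named vector of node degrees.
#' @export
degreeCentrality <- function(binaryAdj) {
  if (!all(binaryAdj %in% c(0, 1)))
    stop("degree centrality is defined on a binarized adjacency matrix")
  rowSums(binaryAdj)
}

# connectivity check for the disconnected-graph log message
.isConnected <- function(B) {
  R <- nrow(B)
  seen <- logical(R)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    nb <- which(B[queue[1L], ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue[-1L], nb)
  }
  all(seen)
}

#' Eigenvector centrality of a binary graph
#'
#' The entrywise non-negative leading eigenvector of the adjacency matrix
#' (Perron-Frobenius convention), normalized to unit Euclidean norm.
#' Isolated nodes score 0. On disconnected graphs the leading eigenvector
#' of the whole matrix is used (nodes outside the dominant component may
#' score ~0), reported via a message.
#'
#' @param binaryAdj binary symmetric adjacency matrix.
#' @param warnDisconnected report disconnected input (default TRUE; the
#'   density sweep disables it to avoid repeated messages).
#' @return non-negative named vector with unit Euclidean norm (all zeros for
#'   an empty graph, with a warning).
#' @export
eigenvectorCentrality <- function(binaryAdj, warnDisconnected = TRUE) {
  if (!all(binaryAdj %in% c(0, 1)))
    stop("eigenvector centrality is defined on a binarized adjacency matrix")
  if (all(binaryAdj == 0)) {
    warning("empty graph: eigenvector centrality undefined, returning zeros")
    return(stats::setNames(numeric(nrow(binaryAdj)), rownames(binaryAdj)))
  }
  if (warnDisconnected && !.isConnected(binaryAdj))
    message("graph is disconnected: using the leading eigenvector of the whole matrix")
  e <- eigen(binaryAdj, symmetric = TRUE)
  v <- abs(e$vectors[, 1L])
  v <- v / sqrt(sum(v^2))
  stats::setNames(v, rownames(binaryAdj))
}

#' Centrality across a grid of network densities
#'
#' Sweeps proportional density thresholds over the adjacency matrix and
#' stacks the chosen centrality at each density. The degree sweep exploits
#' the nesting of thresholded edge sets (edges are sorted once and
#' accumulated), which is exactly equivalent to thresholding at each
#' density separately.
#'
#' @param adj weighted adjacency matrix from [correlationAdjacency()].
#' @param metric "degree" or "eigenvector".
#' @param densities ascending density grid in (0, 1]; default 0.10-0.50 in
#'   1% steps.
#' @return a [CentralityCurve-class].
#' @export
centralityCurve <- function(adj, metric = c("degree", "eigenvector"),
                            densities = seq(0.10, 0.50, by = 0.01)) {
  metric <- match.arg(metric)
  densities <- as.numeric(densities)
  R <- nrow(adj)
  V <- matrix(0, length(densities), R,
              dimnames = list(NULL, rownames(adj)))
  if (metric == "degree") {
    ed <- .sortedEdges(adj)
    ks <- pmin(floor(densities * ed$nPossible + 1e-9), length(ed$w))
    deg <- numeric(R)
    prev <- 0L
    for (d in seq_along(ks)) {
      if (ks[d] > prev) {
        sl <- seq(prev + 1L, ks[d])
        deg <- deg + tabulate(c(ed$i[sl], ed$j[sl]), nbins = R)
        prev <- ks[d]
      }
      V[d, ] <- deg
    }
  } else {
    disconnected <- FALSE
    for (d in seq_along(densities)) {
      B <- thresholdAtDensity(adj, densities[d])
      if (!disconnected && any(rowSums(B) == 0)) disconnected <- TRUE
      V[d, ] <- suppressWarnings(
        eigenvectorCentrality(B, warnDisconnected = FALSE))
    }
    if (disconnected)
      message("some thresholded graphs are disconnected (isolated nodes)")
  }
  new("CentralityCurve", densities = densities, values = V, metric = metric)
}

#' Area under the centrality-vs-density curve
#'
#' Summarizes each region's centrality over the density window
#' `[lo, hi]`. The default convention is the plain sum of the centrality
#' values over the grid points in the window (41 points for the default 1%
#' grid over 10-50%); a trapezoidal integral over density is available as
#' an alternative.
#'
#' @param curve a [CentralityCurve-class].
#' @param lo,hi density window, must be covered by the curve's grid.
#' @param convention "sum" (default) or "trapezoid".
#' @return data.frame with columns `region`, `metric`, `auc`.
#' @export
curveAUC <- function(curve, lo = 0.10, hi = 0.50,
                     convention = c("sum", "trapezoid")) {
  convention <- match.arg(convention)
  sel <- curve@densities >= lo - 1e-9 & curve@densities <= hi + 1e-9
  if (!any(sel)) stop("no density grid points inside [lo, hi]")
  V <- curve@values[sel, , drop = FALSE]
  d <- curve@densities[sel]
  auc <- if (convention == "sum") colSums(V)
         else if (length(d) < 2L) stop("trapezoid needs >= 2 grid points")
         else as.numeric(crossprod(V, c(diff(d) / 2, 0) + c(0, diff(d) / 2)))
  data.frame(region = colnames(curve@values), metric = curve@metric,
             auc = as.numeric(auc), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Write an adjacency matrix as TSV with a region-label header
#' @param adj matrix with dimnames.
#' @param path output path.
#' @export
writeAdjacency <- function(adj, path) {
  df <- data.frame(region = rownames(adj), signif(adj, 10),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
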