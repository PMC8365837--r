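# Adjacency construction, proportional thresholding, centrality, AUC.

test_that("correlation adjacency applies the diagonal and negativity rules", {
  set.seed(31)
  x <- rnorm(30)
  Y <- cbind(a = x, b = x, c = -x + rnorm(30, sd = 1e-8), d = rnorm(30))
  A <- correlationAdjacency(regionTimeseries(Y, 2))
  expect_equal(unname(diag(A)), rep(0, 4))
  expect_equal(A["a", "b"], 1)
  expect_equal(A["a", "c"], 0)          # negative correlation zeroed
  expect_true(all(A >= 0 & A <= 1))
  expect_equal(A, t(A))

  Yc <- Y; Yc[, 2] <- 5
  expect_error(correlationAdjacency(regionTimeseries(Yc, 2)), "b")
})

test_that("a 102-region timeseries gives a 102 x 102 adjacency", {
  set.seed(32)
  Y <- matrix(rnorm(50 * 102), 50, 102)
  colnames(Y) <- modifiedParcellation()
  A <- correlationAdjacency(regionTimeseries(Y, 2.16))
  expect_equal(dim(A), c(102L, 102L))
})

test_that("adjacency and downstream AUC are scale invariant", {
  ts <- makeTimeseries(nT = 40, R = 6, seed = 33)
  sc <- tsMatrix(ts) * rep(c(2, 0.1, 7, 1, 100, 0.5),
                           each = nVolumes(ts))
  colnames(sc) <- regionLabels(ts)
  ts2 <- regionTimeseries(sc, repetitionTime(ts))
  expect_equal(correlationAdjacency(ts), correlationAdjacency(ts2),
               tolerance = 1e-12)
  c1 <- centralityCurve(correlationAdjacency(ts), "degree")
  c2 <- centralityCurve(correlationAdjacency(ts2), "degree")
  expect_equal(c1@values, c2@values)
})

test_that("thresholding keeps the k strongest edges", {
  # 4-node complete graph, distinct weights, density 0.5 -> 3 largest edges
  W <- matrix(0, 4, 4)
  W[upper.tri(W)] <- c(0.9, 0.2, 0.8, 0.4, 0.7, 0.1)
  W <- W + t(W); dimnames(W) <- list(paste0("n", 1:4), paste0("n", 1:4))
  B <- thresholdAtDensity(W, 0.5)
  expect_equal(sum(B[upper.tri(B)]), 3)
  expect_equal(B, oracleThreshold(W, 0.5))

  # full density with all-positive weights keeps everything
  Wp <- makeWeights(7, seed = 34)
  expect_equal(sum(thresholdAtDensity(Wp, 1)[upper.tri(Wp)]), 21)

  # zero-weight edges are never retained
  Wz <- Wp; Wz[Wz < 0.6] <- 0; Wz <- (Wz + t(Wz)) / 2; diag(Wz) <- 0
  Bz <- thresholdAtDensity(Wz, 1)
  expect_equal(sum(Bz[upper.tri(Bz)]), sum(Wz[upper.tri(Wz)] > 0))

  expect_error(thresholdAtDensity(Wp, 0), "density")
  expect_error(thresholdAtDensity(Wp, 1.2), "density")
})

test_that("thresholding matches the sort-and-count oracle on random graphs", {
  for (seed in 1:5) {
    W <- makeWeights(9, seed = seed)
    W[W < 0.3] <- 0; W <- (W + t(W)) / 2; diag(W) <- 0
    for (d in c(0.1, 0.25, 0.5, 0.8)) {
      expect_equal(thresholdAtDensity(W, d), oracleThreshold(W, d))
    }
  }
})

test_that("edge sets are nested across densities", {
  W <- makeWeights(12, seed = 35)
  prev <- thresholdAtDensity(W, 0.05)
  for (d in seq(0.1, 1, by = 0.05)) {
    cur <- thresholdAtDensity(W, d)
    expect_true(all(cur[prev == 1] == 1))
    prev <- cur
  }
})

test_that("degree centrality is the row sum of the binary graph", {
  star <- adjFromEdges(5, list(c(1, 2), c(1, 3), c(1, 4), c(1, 5)))
  expect_equal(unname(degreeCentrality(star)), c(4, 1, 1, 1, 1))
  expect_equal(unname(degreeCentrality(matrix(0, 3, 3))), rep(0, 3))
  expect_error(degreeCentrality(star * 0.5), "binarized")

  # Erdos-Renyi sample vs per-node edge enumeration
  set.seed(36)
  edges <- list()
  for (i in 1:9) for (j in (i + 1):10)
    if (runif(1) < 0.4) edges[[length(edges) + 1]] <- c(i, j)
  B <- adjFromEdges(10, edges)
  cnt <- integer(10)
  for (e in edges) { cnt[e[1]] <- cnt[e[1]] + 1L; cnt[e[2]] <- cnt[e[2]] + 1L }
  expect_equal(unname(degreeCentrality(B)), cnt)
})

test_that("eigenvector centrality matches dense eigensolver oracles", {
  # k-regular connected graph (cycle): all scores 1/sqrt(R)
  cyc <- adjFromEdges(6, lapply(1:6, function(i) c(i, i %% 6 + 1)))
  expect_equal(unname(eigenvectorCentrality(cyc)), rep(1 / sqrt(6), 6),
               tolerance = 1e-10)

  # path on 3 nodes: scores proportional to (1, sqrt(2), 1)
  p3 <- adjFromEdges(3, list(c(1, 2), c(2, 3)))
  v <- unname(eigenvectorCentrality(p3))
  ref <- c(1, sqrt(2), 1); ref <- ref / sqrt(sum(ref^2))
  expect_equal(v, ref, tolerance = 1e-10)

  # empty graph: zeros with a warning
  expect_warning(z <- eigenvectorCentrality(matrix(0, 4, 4)), "empty")
  expect_equal(unname(z), rep(0, 4))

  # random connected graphs vs dense eigendecomposition
  set.seed(37)
  for (rep in 1:10) {
    R <- sample(5:20, 1)
    W <- matrix(rbinom(R * R, 1, 0.5), R, R)
    W[lower.tri(W, diag = TRUE)] <- 0
    B <- W + t(W)
    B[1, 2:R] <- 1; B[2:R, 1] <- 1  # force connectivity
    ec <- eigenvectorCentrality(B)
    ev <- eigen(B, symmetric = TRUE)$vectors[, 1]
    ev <- abs(ev) / sqrt(sum(ev^2))
    expect_lt(max(abs(unname(ec) - ev)), 1e-8)
  }
})

test_that("centrality matches igraph on random binary graphs", {
  skip_if_not_installed("igraph")
  set.seed(38)
  for (rep in 1:5) {
    R <- 12
    B <- matrix(rbinom(R * R, 1, 0.4), R, R)
    B[lower.tri(B, diag = TRUE)] <- 0
    B <- B + t(B)
    B[1, 2:R] <- 1; B[2:R, 1] <- 1
    g <- igraph::graph_from_adjacency_matrix(B, mode = "undirected")
    expect_equal(unname(degreeCentrality(B)), igraph::degree(g))
    eci <- igraph::eigen_centrality(g)$vector
    eci <- eci / sqrt(sum(eci^2))
    expect_equal(unname(eigenvectorCentrality(B)), unname(eci),
                 tolerance = 1e-6)
  }
})

test_that("centrality curves agree with per-density computation", {
  W <- makeWeights(15, seed = 39)
  W[W < 0.35] <- 0; W <- (W + t(W)) / 2; diag(W) <- 0
  dens <- seq(0.10, 0.50, by = 0.01)
  cd <- centralityCurve(W, "degree", dens)
  ce <- suppressMessages(centralityCurve(W, "eigenvector", dens))
  for (k in c(1, 7, 21, 41)) {
    B <- thresholdAtDensity(W, dens[k])
    expect_equal(cd@values[k, ], degreeCentrality(B))
    expect_equal(ce@values[k, ],
                 suppressWarnings(
                   eigenvectorCentrality(B, warnDisconnected = FALSE)),
                 tolerance = 1e-10)
    expect_equal(sum(ce@values[k, ]^2), 1, tolerance = 1e-10)
  }
  # degree curves are non-decreasing in density for every region
  expect_true(all(apply(cd@values, 2, function(v) all(diff(v) >= 0))))
  # single-density grid equals the direct call
  one <- centralityCurve(W, "degree", 0.3)
  expect_equal(one@values[1, ], degreeCentrality(thresholdAtDensity(W, 0.3)))
})

test_that("curve AUC follows the sum convention (trapezoid optional)", {
  dens <- seq(0.10, 0.50, by = 0.01)
  Vconst <- matrix(7, length(dens), 2,
                   dimnames = list(NULL, c("a", "b")))
  cc <- new("CentralityCurve", densities = dens, values = Vconst,
            metric = "degree")
  expect_equal(curveAUC(cc)$auc, c(41 * 7, 41 * 7))

  cc0 <- new("CentralityCurve", densities = dens,
             values = Vconst * 0, metric = "degree")
  expect_equal(curveAUC(cc0)$auc, c(0, 0))

  # linear ramp vs explicit loop oracle
  ramp <- matrix(seq_along(dens), length(dens), 1,
                 dimnames = list(NULL, "a"))
  ccr <- new("CentralityCurve", densities = dens, values = ramp,
             metric = "degree")
  acc <- 0
  for (i in seq_along(dens))
    if (dens[i] >= 0.2 && dens[i] <= 0.4) acc <- acc + ramp[i, 1]
  expect_equal(curveAUC(ccr, 0.2, 0.4)$auc, unname(acc))

  # trapezoid on a constant curve integrates to c * (hi - lo)
  expect_equal(curveAUC(cc, convention = "trapezoid")$auc,
               c(7 * 0.4, 7 * 0.4), tolerance = 1e-12)
  expect_error(curveAUC(cc, 0.6, 0.7), "grid")
})

test_that("AUC magnitude is plausible for a 102-region default sweep", {
  set.seed(40)
  Y <- matrix(rnorm(80 * 102), 80, 102) +
    0.8 * matrix(rnorm(80), 80, 1)[, rep(1, 102)]
  colnames(Y) <- modifiedParcellation()
  A <- correlationAdjacency(regionTimeseries(Y, 2.16))
  auc <- curveAUC(centralityCurve(A, "degree"))$auc
  expect_true(all(auc >= 0 & auc <= 41 * 101))
  expect_gt(stats::median(auc), 200)  # a dense-ish graph, not degenerate
})
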