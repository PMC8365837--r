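# Shared fixture builders. All data are generated in code at test time.

# small random region timeseries with unique labels
makeTimeseries <- function(nT = 40, R = 5, tr = 2, seed = 1) {
  set.seed(seed)
  Y <- matrix(rnorm(nT * R), nT, R)
  colnames(Y) <- paste0("roi", seq_len(R))
  regionTimeseries(Y, tr = tr, subjectId = "sub-test")
}

# random symmetric non-negative weight matrix with zero diagonal
makeWeights <- function(R = 8, seed = 1) {
  set.seed(seed)
  W <- matrix(runif(R * R), R, R)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  dimnames(W) <- list(paste0("n", 1:R), paste0("n", 1:R))
  W
}

# binary adjacency from an edge list on R nodes
adjFromEdges <- function(R, edges) {
  B <- matrix(0, R, R)
  for (e in edges) { B[e[1], e[2]] <- 1; B[e[2], e[1]] <- 1 }
  dimnames(B) <- list(paste0("n", 1:R), paste0("n", 1:R))
  B
}

# independent sort-and-count thresholding oracle: the k largest positive
# upper-triangle weights, ties by (i, j)
oracleThreshold <- function(W, density) {
  R <- nrow(W)
  ut <- which(upper.tri(W), arr.ind = TRUE)
  w <- W[ut]
  o <- order(-w, ut[, 1], ut[, 2])
  k <- min(floor(density * R * (R - 1) / 2 + 1e-9), sum(w > 0))
  B <- matrix(0, R, R, dimnames = dimnames(W))
  if (k > 0) for (idx in o[seq_len(k)]) {
    B[ut[idx, 1], ut[idx, 2]] <- 1
    B[ut[idx, 2], ut[idx, 1]] <- 1
  }
  B
}

# small cohort spec for pipeline-level tests (cheap but full-featured);
# any default below can be overridden through ...
smallCohortSpec <- function(...) {
  args <- list(nPatients = 3, nControls = 3, nRegions = 12, nVolumes = 80,
               regionLabels = c(paste0("Ctx", 1:5, "_L"),
                                paste0("Ctx", 1:5, "_R"), "Hub_L",
                                "Hub_R"),
               hubRegions = c("Hub_L", "Hub_R"),
               hubTargets = c("Ctx1_L", "Ctx1_R", "Ctx2_L", "Ctx2_R"),
               iedRegions = c("Ctx4_L", "Ctx4_R"),
               iedCountRange = c(2, 20), nSpikeTypesRange = c(1, 2),
               nBlocks = 3, nLeftEZ = 2)
  over <- list(...)
  args[names(over)] <- over
  do.call(cohortSpec, args)
}
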