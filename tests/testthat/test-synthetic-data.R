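# Synthetic cohort generator: dimensions, event model, determinism,
# correlation recovery.

test_that("default cohort spec mirrors the study design", {
  spec <- cohortSpec()
  expect_equal(spec@nPatients, 35L)
  expect_equal(spec@nControls, 20L)
  expect_equal(spec@nRegions, 102L)
  expect_equal(spec@nVolumes, 295L)
  expect_equal(spec@tr, 2.16)
  expect_equal(spec@iedCountRange, c(2, 450))
  expect_equal(spec@nSpikeTypesRange, c(1, 4))
  expect_equal(spec@nLeftEZ, 20L)
  expect_equal(spec@hubRegions, c("Thalamus_Ant_L", "Thalamus_Ant_R"))
  expect_length(spec@regionLabels, 102)
  # planted targets never overlap the hub or the IED-response set
  expect_false(any(spec@hubRegions %in% spec@hubTargets))
  expect_false(any(spec@iedRegions %in% spec@hubTargets))
  expect_error(cohortSpec(nPatients = 1), "2 subjects")
  expect_error(cohortSpec(hubRegions = c("nope_L", "nope_R")), "hubRegions")
})

test_that("generated subjects have the specified geometry and metadata", {
  spec <- cohortSpec(nPatients = 4, nControls = 3, nLeftEZ = 3, seed = 60)
  ch <- generateCohort(spec)
  expect_length(ch$subjects, 7)
  ts1 <- ch$subjects[[1]]$ts
  expect_equal(dim(tsMatrix(ts1)), c(295L, 102L))
  expect_equal(regionLabels(ts1), modifiedParcellation())
  expect_equal(sum(ch$meta$group == "patient"), 4)
  expect_equal(sum(ch$meta$ezLaterality == "left"), 3)
  expect_true(all(ch$meta$ezLaterality[ch$meta$group == "control"] ==
                  "none"))
  expect_equal(ncol(ch$subjects[[1]]$confounds), 12)

  pat <- which(ch$meta$group == "patient")
  for (k in pat) {
    nEv <- sum(vapply(ch$subjects[[k]]$events, length, 1L))
    expect_equal(nEv, ch$meta$totalSpikes[k])
    expect_gte(nEv, spec@iedCountRange[1])
    expect_lte(nEv, spec@iedCountRange[2])
    expect_gte(length(ch$subjects[[k]]$events), 1)
    expect_lte(length(ch$subjects[[k]]$events), 4)
  }
  expect_true(all(ch$meta$totalSpikes[ch$meta$group == "control"] == 0))
})

test_that("cohort generation is deterministic under a fixed seed", {
  spec <- smallCohortSpec(seed = 61)
  a <- generateCohort(spec)
  b <- generateCohort(spec)
  expect_identical(tsMatrix(a$subjects[[2]]$ts),
                   tsMatrix(b$subjects[[2]]$ts))
  expect_identical(a$meta, b$meta)
  expect_identical(a$subjects[[1]]$events[[1]]@onsets,
                   b$subjects[[1]]$events[[1]]@onsets)
})

test_that("long series recover the planted correlations", {
  spec <- cohortSpec(nPatients = 2, nControls = 2, nRegions = 20,
                     nVolumes = 5000,
                     regionLabels = c(paste0("R", 1:18), "Hub_L", "Hub_R"),
                     hubRegions = c("Hub_L", "Hub_R"),
                     hubTargets = paste0("R", 1:4),
                     iedAmplitude = 0, hubEffect = 0.2, nBlocks = 3,
                     nLeftEZ = 2, seed = 62)
  ch <- generateCohort(spec)
  # patient 1 (left EZ): hub-target correlation ~ base (0, cross-block)
  # + hubEffect, after removing the mixed-in confounds
  sub <- ch$subjects[[1]]
  clean <- tsMatrix(regressConfounds(sub$ts, sub$confounds))
  cc <- cor(clean[, "Hub_L"], clean[, "R1"])
  expect_lt(abs(cc - 0.2), 0.05)
  # within-block background correlation
  cb <- cor(clean[, "R1"], clean[, "R2"])
  expect_lt(abs(cb - 0.3), 0.05)
  # controls carry no planted effect
  sub4 <- ch$subjects[[4]]
  clean4 <- tsMatrix(regressConfounds(sub4$ts, sub4$confounds))
  expect_lt(abs(cor(clean4[, "Hub_L"], clean4[, "R1"])), 0.05)
})

test_that("IED responses raise correlation among the carrier regions", {
  spec <- smallCohortSpec(hubEffect = 0, iedAmplitude = 5,
                          iedCountRange = c(5, 10), nVolumes = 200,
                          seed = 63)
  ch <- generateCohort(spec)
  pat <- which(ch$meta$group == "patient")[1]
  ctl <- which(ch$meta$group == "control")[1]
  corAt <- function(k) {
    Y <- tsMatrix(ch$subjects[[k]]$ts)
    cor(Y[, "Ctx4_L"], Y[, "Ctx4_R"])
  }
  expect_gt(corAt(pat), corAt(ctl) + 0.2)
})

test_that("the micro example is small, deterministic and well-formed", {
  ch <- generateMicroExample()
  expect_length(ch$subjects, 4)
  expect_equal(dim(tsMatrix(ch$subjects[[1]]$ts)), c(60L, 6L))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeCohort(generateMicroExample(), d1)
  writeCohort(generateMicroExample(), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # adjacency contract holds on the fixture
  A <- correlationAdjacency(
    bandpass(regressConfounds(ch$subjects[[1]]$ts,
                              ch$subjects[[1]]$confounds)))
  expect_equal(unname(diag(A)), rep(0, 6))
  expect_true(all(A >= 0 & A <= 1))
  # degree at half density matches the sort-and-count oracle
  expect_equal(degreeCentrality(thresholdAtDensity(A, 0.5)),
               degreeCentrality(oracleThreshold(A, 0.5)))
})

test_that("cohorts round-trip through the on-disk layout", {
  ch <- generateMicroExample()
  d <- withr::local_tempdir()
  writeCohort(ch, d)
  back <- readCohort(d)
  expect_equal(back$meta$subjectId, ch$meta$subjectId)
  expect_equal(back$meta$totalSpikes, ch$meta$totalSpikes)
  expect_equal(tsMatrix(back$subjects[[3]]$ts),
               tsMatrix(ch$subjects[[3]]$ts), tolerance = 1e-8)
  expect_equal(length(back$subjects[[1]]$events),
               length(ch$subjects[[1]]$events))
  expect_equal(back$subjects[[1]]$events[[1]]@onsets,
               ch$subjects[[1]]$events[[1]]@onsets, tolerance = 1e-8)
})

test_that("an over-strong planted effect is repaired to a valid covariance", {
  spec <- smallCohortSpec(hubEffect = 0.9, seed = 64)
  expect_message(ch <- generateCohort(spec), "repaired")
  expect_equal(dim(tsMatrix(ch$subjects[[1]]$ts)), c(80L, 12L))
})

test_that("the pipeline reproduces the shipped micro-example fixtures", {
  ch <- generateMicroExample()
  cfg <- pipelineConfig(metrics = "degree", iedCorrection = "off",
                        nPermutations = 49)
  auc <- cohortAUCTable(ch, cfg)
  exp <- read.delim(system.file("extdata", "micro", "expected_dc_auc.tsv",
                                package = "thalfc"),
                    stringsAsFactors = FALSE)
  key <- paste(auc$subjectId, auc$region)
  expect_equal(auc$auc[match(paste(exp$subjectId, exp$region), key)],
               exp$auc)

  sub <- ch$subjects[[1]]
  A <- correlationAdjacency(
    bandpass(regressConfounds(sub$ts, sub$confounds)))
  expA <- read.delim(system.file("extdata", "micro",
                                 "expected_adjacency_sub-001.tsv",
                                 package = "thalfc"),
                     check.names = FALSE)
  expect_equal(unname(A), unname(as.matrix(expA[, -1])), tolerance = 1e-8)
})
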