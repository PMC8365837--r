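# Synthetic EEG-fMRI cohorts with the statistical structure the analysis
# assumes: band-limited multivariate Gaussian background with block
# correlation structure, an optional planted connectivity increase between
# an ipsilateral "hub" and a cortical target set in patients, HRF-locked
# IED responses, and partially mixed-in nuisance confounds.

# Band-limited unit-variance Gaussian noise, one column per region: white
# Gaussian noise ideal-band filtered to [low, high] Hz, drawn directly in
# the frequency domain (the two constructions are the same process).
.bandlimitedNoise <- function(nT, R, fs, low, high) {
  nF <- stats::nextn(nT, c(2, 3, 5))  # FFT-friendly length, then truncate
  k <- seq_len(floor((nF - 1) / 2))
  keep <- k[k * fs / nF >= low & k * fs / nF <= high]
  if (!length(keep)) stop("no frequency bins inside the generation band")
  X <- matrix(0 + 0i, nF, R)
  Z <- matrix(complex(real = rnorm(length(keep) * R),
                      imaginary = rnorm(length(keep) * R)),
              length(keep), R)
  X[keep + 1L, ] <- Z
  X[nF + 1L - keep, ] <- Conj(Z)
  E <- Re(stats::mvfft(X, inverse = TRUE))[seq_len(nT), , drop = FALSE]
  m <- colMeans(E)
  s <- sqrt(pmax(colMeans(E^2) - m^2, .Machine$double.eps))
  (E - rep(m, each = nT)) * rep(1 / s, each = nT)
}

# eigenvalue clipping to the nearest correlation matrix with min eigenvalue
# >= eps (rescaled to unit diagonal)
.nearestPSD <- function(S, eps = 1e-8) {
  e <- eigen(S, symmetric = TRUE)
  v <- pmax(e$values, eps)
  S2 <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(S2))
  S2 <- S2 / tcrossprod(d)
  diag(S2) <- 1
  (S2 + t(S2)) / 2
}

.defaultLabels <- function(nRegions) {
  if (nRegions == 102L) return(modifiedParcellation())
  if (nRegions < 4L) stop("need at least 4 regions")
  lab <- sprintf("Region_%03d", seq_len(nRegions - 2L))
  c(lab, "Hub_L", "Hub_R")
}

#' Specify a synthetic cohort
#'
#' Builds a [CohortSpec-class] whose defaults emulate the target study
#' design: 35 patients vs 20 controls (EZ lateralized left in 20), 295
#' volumes at TR 2.16 s, 102 regions, per-session IED totals between 2 and
#' 450 spread over 1-4 spike types, a planted correlation increase between
#' the ipsilateral anterior-thalamic hub and a frontal cortical target set
#' in patients, and HRF-locked IED responses on a posterior cortical set.
#'
#' @param nPatients,nControls group sizes.
#' @param nRegions,nVolumes,tr scan geometry.
#' @param regionLabels region names (defaults to [modifiedParcellation()]
#'   when `nRegions` is 102).
#' @param hubRegions left/right labels of the planted hub pair.
#' @param hubTargets cortical regions receiving the planted hub correlation
#'   (default: the first 20 cortical labels, a frontal set).
#' @param hubEffect added correlation on ipsilateral hub-target pairs in
#'   patients (default 0.20, calibrated by a pilot power sweep at the
#'   design sample sizes; 0 gives exchangeable groups).
#' @param iedRegions regions carrying the IED-locked response.
#' @param iedAmplitude IED response amplitude in background-signal SD units.
#' @param iedCountRange,nSpikeTypesRange,iedDurationRange IED event model.
#' @param noiseSd,nBlocks,blockRho,confoundMix background signal model.
#' @param nLeftEZ patients with a left EZ (default scales the 20:15 split).
#' @param seed default seed used by [generateCohort()] (NA: current RNG).
#' @return a validated [CohortSpec-class].
#' @export
cohortSpec <- function(nPatients = 35, nControls = 20, nRegions = 102,
                       nVolumes = 295, tr = 2.16,
                       regionLabels = .defaultLabels(nRegions),
                       hubRegions = if (nRegions == 102)
                         c("Thalamus_Ant_L", "Thalamus_Ant_R")
                         else c("Hub_L", "Hub_R"),
                       hubTargets = NULL, hubEffect = 0.20,
                       iedRegions = NULL, iedAmplitude = 1,
                       iedCountRange = c(2, 450),
                       nSpikeTypesRange = c(1, 4),
                       iedDurationRange = c(0, 1), noiseSd = 0.25,
                       nBlocks = 6, blockRho = 0.3, confoundMix = 0.3,
                       nLeftEZ = round(nPatients * 20 / 35), seed = NA) {
  nonHub <- setdiff(regionLabels, hubRegions)
  if (is.null(hubTargets))
    hubTargets <- head(nonHub, min(20L, length(nonHub) %/% 2L))
  if (is.null(iedRegions)) {
    rest <- setdiff(nonHub, hubTargets)
    iedRegions <- head(rest[!grepl("^Thalamus", rest)],
                       min(10L, length(rest)))
  }
  new("CohortSpec", nPatients = as.integer(nPatients),
      nControls = as.integer(nControls), nRegions = as.integer(nRegions),
      nVolumes = as.integer(nVolumes), tr = tr,
      regionLabels = regionLabels, hubRegions = hubRegions,
      hubTargets = hubTargets, hubEffect = hubEffect,
      iedRegions = iedRegions, iedAmplitude = iedAmplitude,
      iedCountRange = iedCountRange,
      nSpikeTypesRange = nSpikeTypesRange,
      iedDurationRange = iedDurationRange, noiseSd = noiseSd,
      nBlocks = as.integer(nBlocks), blockRho = blockRho,
      confoundMix = confoundMix, nLeftEZ = as.integer(nLeftEZ),
      seed = as.numeric(seed))
}

# the three correlation variants: control, patient-left-EZ, patient-right-EZ
.cohortSigmas <- function(spec) {
  R <- spec@nRegions
  blocks <- rep(seq_len(spec@nBlocks),
                each = ceiling(R / spec@nBlocks))[seq_len(R)]
  S0 <- spec@blockRho * outer(blocks, blocks, "==")
  diag(S0) <- 1
  ti <- match(spec@hubTargets, spec@regionLabels)
  plant <- function(hubLabel) {
    h <- match(hubLabel, spec@regionLabels)
    S <- S0
    S[h, ti] <- pmin(0.99, S[h, ti] + spec@hubEffect)
    S[ti, h] <- S[h, ti]
    S
  }
  sig <- list(control = S0, left = plant(spec@hubRegions[1]),
              right = plant(spec@hubRegions[2]))
  lapply(sig, function(S) {
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < 1e-8) {
      message("implied correlation matrix not positive definite; repaired by nearest-PSD projection")
      S <- .nearestPSD(S)
    }
    chol(S)
  })
}

.drawEventTrains <- function(spec) {
  sessionLen <- spec@nVolumes * spec@tr
  nTypes <- sample(seq(spec@nSpikeTypesRange[1], spec@nSpikeTypesRange[2]),
                   1L)
  total <- round(exp(runif(1, log(spec@iedCountRange[1]),
                           log(spec@iedCountRange[2]))))
  total <- max(spec@iedCountRange[1],
               min(spec@iedCountRange[2], total, na.rm = TRUE))
  nTypes <- min(nTypes, total)
  counts <- if (nTypes == 1L) total else
    as.vector(rmultinom(1, total - nTypes, rep(1, nTypes))) + 1L
  lapply(seq_len(nTypes), function(k)
    eventTrain(runif(counts[k], 0, sessionLen - 1),
               runif(counts[k], spec@iedDurationRange[1],
                     spec@iedDurationRange[2]),
               spikeType = paste0("spike", k)))
}

.nuisanceConfounds <- function(nT) {
  drift <- vapply(1:3, function(k) cos(pi * k * (seq_len(nT) - 1) / (nT - 1)),
                  numeric(nT))
  smooth <- vapply(1:9, function(k) {
    v <- as.numeric(stats::filter(rnorm(nT + 8L), rep(1 / 8, 8L),
                                  sides = 1L))[-seq_len(8L)]
    v / sd(v)
  }, numeric(nT))
  C <- cbind(drift, smooth)
  colnames(C) <- c(paste0("drift", 1:3), paste0("noise", 1:9))
  C
}

#' Generate a synthetic cohort
#'
#' Draws, for every subject, a zero-mean multivariate Gaussian region
#' timeseries whose temporal spectrum is band-limited to 0.01-0.10 Hz (so
#' the 0.04-0.07 Hz analysis band contains signal) and whose correlation
#' follows the block background structure, plus (patients only, ipsilateral
#' side) the planted hub-target increase. Patients additionally receive
#' IED event trains whose canonical-HRF response is superimposed on the
#' configured regions. Twelve nuisance confounds (3 cosine drifts, 9 smooth
#' noise regressors) are partially mixed into the data, and white
#' measurement noise is added.
#'
#' @param spec a [CohortSpec-class].
#' @param seed RNG seed; default is `spec@seed` (NA: use the current RNG
#'   stream, which keeps replicate loops deterministic under one outer
#'   seed).
#' @return list with elements `subjects` (per subject: `ts` a
#'   [RegionTimeseries-class], `events` a list of [EventTrain-class],
#'   `confounds` a matrix), `meta` (data.frame with `subjectId`, `group`,
#'   `ezLaterality`, `totalSpikes`, `spikeCounts`) and `spec`.
#' @export
generateCohort <- function(spec, seed = spec@seed) {
  if (!is.na(seed)) set.seed(seed)
  U <- .cohortSigmas(spec)
  nT <- spec@nVolumes; R <- spec@nRegions
  fs <- 1 / spec@tr
  basis <- canonicalHRF(dt = spec@tr / 16)
  iedIdx <- match(spec@iedRegions, spec@regionLabels)

  lat <- sample(c(rep("left", spec@nLeftEZ),
                  rep("right", spec@nPatients - spec@nLeftEZ)))
  groups <- c(rep("patient", spec@nPatients),
              rep("control", spec@nControls))

  subjects <- vector("list", length(groups))
  meta <- vector("list", length(groups))
  for (s in seq_along(groups)) {
    sid <- sprintf("sub-%03d", s)
    isPat <- groups[s] == "patient"
    side <- if (isPat) lat[s] else "none"

    Y <- .bandlimitedNoise(nT, R, fs, 0.01, 0.10) %*%
      U[[if (isPat) side else "control"]]

    events <- list()
    counts <- integer(0)
    if (isPat) {
      events <- .drawEventTrains(spec)
      counts <- vapply(events, length, 1L)
      if (spec@iedAmplitude != 0 && length(iedIdx)) {
        dm <- buildEventRegressors(events, basis, nT, spec@tr)
        resp <- rowSums(dm@data[, grep("canonical", colnames(dm@data)),
                                drop = FALSE])
        m <- max(abs(resp))
        if (m > 0)
          Y[, iedIdx] <- Y[, iedIdx] + spec@iedAmplitude * resp / m
      }
    }

    C <- .nuisanceConfounds(nT)
    Y <- Y + C %*% matrix(rnorm(ncol(C) * R, sd = spec@confoundMix),
                          ncol(C), R)
    Y <- Y + matrix(rnorm(nT * R, sd = spec@noiseSd), nT, R)
    colnames(Y) <- spec@regionLabels

    subjects[[s]] <- list(ts = regionTimeseries(Y, spec@tr, subjectId = sid),
                          events = events, confounds = C)
    meta[[s]] <- data.frame(subjectId = sid, group = groups[s],
                            ezLaterality = side,
                            totalSpikes = sum(counts),
                            spikeCounts = paste(counts, collapse = ","),
                            stringsAsFactors = FALSE)
  }
  list(subjects = subjects, meta = do.call(rbind, meta), spec = spec)
}

#' A tiny deterministic worked example
#'
#' Six regions, 60 volumes, two subjects per group, fixed seed: small
#' enough to verify adjacency construction, thresholding and AUC by hand,
#' and fast enough for examples.
#'
#' @param seed fixed seed (default 42).
#' @return a cohort as returned by [generateCohort()].
#' @export
generateMicroExample <- function(seed = 42) {
  spec <- cohortSpec(nPatients = 2, nControls = 2, nRegions = 6,
                     nVolumes = 60,
                     regionLabels = c("CtxA_L", "CtxA_R", "CtxB_L",
                                      "CtxB_R", "Hub_L", "Hub_R"),
                     hubRegions = c("Hub_L", "Hub_R"),
                     hubTargets = c("CtxA_L", "CtxA_R"), hubEffect = 0.3,
                     iedRegions = c("CtxB_L", "CtxB_R"), iedAmplitude = 1,
                     iedCountRange = c(2, 10), nSpikeTypesRange = c(1, 2),
                     nBlocks = 2, nLeftEZ = 1, seed = seed)
  generateCohort(spec)
}

#' Write a cohort in the formats the pipeline reads
#'
#' Per subject: `<id>_timeseries.tsv` (+ JSON sidecar),
#' `<id>_confounds.tsv`, and for patients `<id>_events.tsv`; cohort
#' metadata in `participants.tsv`.
#'
#' @param cohort as returned by [generateCohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sub in cohort$subjects) {
    sid <- subjectId(sub$ts)
    writeRegionTimeseries(sub$ts, file.path(dir,
                                            paste0(sid, "_timeseries.tsv")))
    write.table(as.data.frame(signif(sub$confounds, 10)),
                file.path(dir, paste0(sid, "_confounds.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (length(sub$events))
      writeEvents(sub$events, file.path(dir, paste0(sid, "_events.tsv")))
  }
  write.table(cohort$meta, file.path(dir, "participants.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by [writeCohort()]
#'
#' @param dir cohort directory containing `participants.tsv`.
#' @return a cohort list (`spec` is NULL for cohorts read from disk).
#' @export
readCohort <- function(dir) {
  meta <- utils::read.delim(file.path(dir, "participants.tsv"),
                            stringsAsFactors = FALSE,
                            colClasses = c(spikeCounts = "character"))
  subjects <- lapply(meta$subjectId, function(sid) {
    ts <- readRegionTimeseries(file.path(dir,
                                         paste0(sid, "_timeseries.tsv")))
    cf <- as.matrix(utils::read.delim(
      file.path(dir, paste0(sid, "_confounds.tsv")), check.names = FALSE))
    evPath <- file.path(dir, paste0(sid, "_events.tsv"))
    ev <- if (file.exists(evPath)) readEvents(evPath) else list()
    list(ts = ts, events = ev, confounds = cf)
  })
  list(subjects = subjects, meta = meta, spec = NULL)
}
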