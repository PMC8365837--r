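#' @import methods
#' @importFrom stats median cor rnorm runif rmultinom qnorm pnorm pt sd
#' @importFrom utils read.delim write.table head
NULL

#' Region-by-time BOLD timeseries
#'
#' Container for a subject's region-mean BOLD signal: a numeric matrix with
#' one row per acquired volume and one column per parcellation region, plus
#' the repetition time (TR, seconds) and a subject identifier. Region labels
#' are the column names.
#'
#' @slot data numeric matrix, volumes x regions; no missing values.
#' @slot tr repetition time in seconds.
#' @slot subjectId subject identifier.
#' @export
setClass("RegionTimeseries",
  representation(data = "matrix", tr = "numeric", subjectId = "character"),
  validity = function(object) {
    d <- object@data
    if (!is.numeric(d)) return("data must be a numeric matrix")
    if (anyNA(d)) return("data must not contain missing values")
    if (nrow(d) < 2L) return("need at least 2 volumes")
    if (ncol(d) < 2L) return("need at least 2 regions")
    lab <- colnames(d)
    if (is.null(lab) || anyDuplicated(lab) || any(!nzchar(lab)))
      return("region labels (column names) must be unique and non-empty")
    if (length(object@tr) != 1L || !is.finite(object@tr) || object@tr <= 0)
      return("tr must be a single positive number")
    if (length(object@subjectId) != 1L) return("subjectId must be length 1")
    TRUE
  })

#' A train of interictal epileptiform discharge (IED) events
#'
#' Onsets and durations, in seconds from session start, of all marked events
#' of one spike type. Zero duration encodes an impulse event.
#'
#' @slot onsets numeric, non-negative, sorted ascending.
#' @slot durations numeric, non-negative, same length as onsets.
#' @slot spikeType single categorical label shared by all events.
#' @export
setClass("EventTrain",
  representation(onsets = "numeric", durations = "numeric",
                 spikeType = "character"),
  validity = function(object) {
    if (length(object@onsets) != length(object@durations))
      return("onsets and durations must have equal length")
    if (length(object@onsets) && any(object@onsets < 0))
      return("onsets must be non-negative")
    if (is.unsorted(object@onsets)) return("onsets must be sorted ascending")
    if (length(object@durations) && any(object@durations < 0))
      return("durations must be non-negative")
    if (length(object@spikeType) != 1L)
      return("spikeType must be a single label")
    TRUE
  })

#' Hemodynamic response basis set
#'
#' The canonical double-gamma HRF with its temporal and dispersion
#' derivatives, sampled on a uniform microtime grid.
#'
#' @slot sampleTimes seconds, uniform grid starting at 0 with spacing dt.
#' @slot canonical canonical HRF, scaled to unit peak.
#' @slot temporalDerivative derivative with respect to a 1 s onset shift.
#' @slot dispersionDerivative derivative with respect to peak dispersion.
#' @slot dt microtime resolution in seconds.
#' @slot duration support length in seconds.
#' @slot params the double-gamma parameter set used.
#' @export
setClass("HRFBasis",
  representation(sampleTimes = "numeric", canonical = "numeric",
                 temporalDerivative = "numeric",
                 dispersionDerivative = "numeric",
                 dt = "numeric", duration = "numeric", params = "list"),
  validity = function(object) {
    n <- length(object@sampleTimes)
    if (length(object@canonical) != n ||
        length(object@temporalDerivative) != n ||
        length(object@dispersionDerivative) != n)
      return("basis vectors must all have the length of sampleTimes")
    if (object@dt <= 0 || object@duration <= 0)
      return("dt and duration must be positive")
    TRUE
  })

#' HRF-convolved regressor matrix
#'
#' Event regressors sampled at volume acquisition times: three columns per
#' spike type (canonical, temporal derivative, dispersion derivative).
#'
#' @slot data numeric matrix, volumes x regressors, with column names.
#' @slot tr repetition time in seconds.
#' @export
setClass("DesignMatrix",
  representation(data = "matrix", tr = "numeric"),
  validity = function(object) {
    if (!is.numeric(object@data)) return("data must be numeric")
    if (is.null(colnames(object@data))) return("columns must be named")
    if (object@tr <= 0) return("tr must be positive")
    TRUE
  })

#' Centrality as a function of network density
#'
#' @slot densities ordered grid of retained-edge proportions in (0, 1].
#' @slot values matrix, densities x regions, of centrality values.
#' @slot metric "degree" or "eigenvector".
#' @export
setClass("CentralityCurve",
  representation(densities = "numeric", values = "matrix",
                 metric = "character"),
  validity = function(object) {
    if (is.unsorted(object@densities, strictly = TRUE))
      return("densities must be strictly increasing")
    if (any(object@densities <= 0) || any(object@densities > 1))
      return("densities must lie in (0, 1]")
    if (nrow(object@values) != length(object@densities))
      return("values must have one row per density")
    if (!object@metric %in% c("degree", "eigenvector"))
      return("metric must be 'degree' or 'eigenvector'")
    TRUE
  })

#' Permutation comparison of two groups of AUC values
#'
#' Result of the median-difference permutation test: observed difference of
#' group medians, two-tailed permutation p-value, and Mann-Whitney-based
#' effect size r = z / sqrt(n1 + n2).
#'
#' @slot region region label the comparison refers to ("" when not tied to one).
#' @slot metric centrality metric the AUCs summarize.
#' @slot observedDiff median(x) - median(y).
#' @slot pValue two-tailed permutation p in (0, 1].
#' @slot effectSizeR rank-based effect size, |r| <= 1.
#' @slot nPermutations permutations used (or enumerated assignments).
#' @slot n1,n2 group sizes.
#' @slot method "monte-carlo", "exhaustive" or "sign-flip".
#' @export
setClass("GroupComparison",
  representation(region = "character", metric = "character",
                 observedDiff = "numeric", pValue = "numeric",
                 effectSizeR = "numeric", nPermutations = "numeric",
                 n1 = "integer", n2 = "integer", method = "character"),
  validity = function(object) {
    if (object@pValue <= 0 || object@pValue > 1)
      return("pValue must lie in (0, 1]")
    if (is.finite(object@effectSizeR) && abs(object@effectSizeR) > 1 + 1e-12)
      return("|effectSizeR| must be <= 1")
    TRUE
  })

#' Synthetic cohort specification
#'
#' Parameters of the simulated EEG-fMRI study: cohort sizes, scan geometry,
#' the background correlation structure, the planted ipsilateral-hub
#' connectivity increase, and the IED event/response model. Defaults mirror
#' the study design the package targets: 35 patients vs 20 controls, 295
#' retained volumes at TR 2.16 s, 102 regions, 2-450 IEDs per session over
#' 1-4 spike types, and a 20:15 left:right split of epileptogenic-zone (EZ)
#' laterality.
#'
#' @slot nPatients,nControls group sizes.
#' @slot nRegions,nVolumes matrix dimensions of each subject's timeseries.
#' @slot tr repetition time, seconds.
#' @slot regionLabels region names, length nRegions.
#' @slot hubRegions length-2 character: the left and right planted hub labels.
#' @slot hubTargets cortical regions whose correlation with the ipsilateral
#'   hub is raised by hubEffect in patients.
#' @slot hubEffect added correlation (delta rho) on hub-target pairs.
#' @slot iedRegions regions carrying the IED-locked BOLD response.
#' @slot iedAmplitude amplitude of the IED response in units of the
#'   (unit-variance) background signal.
#' @slot iedCountRange,(nSpikeTypesRange) per-session total IED count range and
#'   spike-type count range.
#' @slot iedDurationRange uniform range of event durations, seconds.
#' @slot noiseSd white measurement-noise SD (background signal has SD 1).
#' @slot nBlocks,blockRho background block-correlation structure.
#' @slot confoundMix SD of the coefficients mixing the 12 nuisance confound
#'   regressors into the data.
#' @slot nLeftEZ number of patients with a left-lateralized EZ.
#' @slot seed default RNG seed (NA = use the current RNG stream).
#' @export
setClass("CohortSpec",
  representation(nPatients = "integer", nControls = "integer",
                 nRegions = "integer", nVolumes = "integer", tr = "numeric",
                 regionLabels = "character", hubRegions = "character",
                 hubTargets = "character", hubEffect = "numeric",
                 iedRegions = "character", iedAmplitude = "numeric",
                 iedCountRange = "numeric", nSpikeTypesRange = "numeric",
                 iedDurationRange = "numeric", noiseSd = "numeric",
                 nBlocks = "integer", blockRho = "numeric",
                 confoundMix = "numeric", nLeftEZ = "integer",
                 seed = "numeric"),
  validity = function(object) {
    if (object@nPatients < 2L || object@nControls < 2L)
      return("need at least 2 subjects per group")
    if (length(object@regionLabels) != object@nRegions)
      return("regionLabels must have length nRegions")
    if (anyDuplicated(object@regionLabels))
      return("regionLabels must be unique")
    if (length(object@hubRegions) != 2L ||
        !all(object@hubRegions %in% object@regionLabels))
      return("hubRegions must be 2 labels present in regionLabels")
    if (!all(object@hubTargets %in% object@regionLabels))
      return("hubTargets must be a subset of regionLabels")
    if (any(object@hubRegions %in% object@hubTargets))
      return("hubTargets must not contain the hub regions")
    if (!all(object@iedRegions %in% object@regionLabels))
      return("iedRegions must be a subset of regionLabels")
    if (length(object@iedCountRange) != 2L ||
        object@iedCountRange[1] < 1 ||
        diff(object@iedCountRange) < 0)
      return("iedCountRange must be an increasing pair of counts >= 1")
    if (length(object@nSpikeTypesRange) != 2L ||
        object@nSpikeTypesRange[1] < 1 ||
        diff(object@nSpikeTypesRange) < 0)
      return("nSpikeTypesRange must be an increasing pair >= 1")
    if (object@nLeftEZ < 0L || object@nLeftEZ > object@nPatients)
      return("nLeftEZ must lie in [0, nPatients]")
    if (object@blockRho < 0 || object@blockRho >= 1)
      return("blockRho must lie in [0, 1)")
    if (object@hubEffect < 0) return("hubEffect must be non-negative")
    if (object@tr <= 0) return("tr must be positive")
    TRUE
  })
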