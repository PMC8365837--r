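# Canonical HRF basis and event-convolved regressors.

.doubleGamma <- function(t, peakDelay, peakDispersion, undershootDelay,
                         undershootDispersion, ratio, onset) {
  tt <- t - onset
  out <- stats::dgamma(tt, shape = peakDelay / peakDispersion,
                       scale = peakDispersion) -
    stats::dgamma(tt, shape = undershootDelay / undershootDispersion,
                  scale = undershootDispersion) / ratio
  out[tt < 0] <- 0
  out
}

#' Default double-gamma HRF parameters
#'
#' The conventional parameter set: response peak delay 6 s, undershoot delay
#' 16 s, both dispersions 1 s, response:undershoot amplitude ratio 6, onset
#' 0 s.
#'
#' @return named list of the six parameters.
#' @export
defaultHRFParams <- function() {
  list(peakDelay = 6, peakDispersion = 1, undershootDelay = 16,
       undershootDispersion = 1, ratio = 6, onset = 0)
}

#' Canonical hemodynamic response basis
#'
#' Builds the canonical double-gamma HRF, scaled to unit peak, together with
#' its temporal derivative (finite difference with respect to a 1 s onset
#' shift) and dispersion derivative (finite difference with respect to the
#' response peak dispersion, perturbation 0.01), all sampled on a uniform
#' microtime grid.
#'
#' @param dt microtime resolution in seconds.
#' @param duration support length in seconds (default 32).
#' @param params double-gamma parameters, see [defaultHRFParams()]; partial
#'   lists are completed with the defaults.
#' @return an [HRFBasis-class] object.
#' @export
#' @examples
#' b <- canonicalHRF(0.1)
#' b@sampleTimes[which.max(b@canonical)]  # ~5 s
canonicalHRF <- function(dt, duration = 32, params = list()) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number")
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("duration must be a single positive number")
  p <- utils::modifyList(defaultHRFParams(), params)
  n <- max(2L, round(duration / dt))
  t <- (seq_len(n) - 1) * dt

  raw <- .doubleGamma(t, p$peakDelay, p$peakDispersion, p$undershootDelay,
                      p$undershootDispersion, p$ratio, p$onset)
  peak <- max(raw)
  if (peak <= 0) stop("degenerate HRF parameters: non-positive peak")

  # onset shifted by +1 s; dispersion perturbed by +0.01
  shifted <- .doubleGamma(t, p$peakDelay, p$peakDispersion, p$undershootDelay,
                          p$undershootDispersion, p$ratio, p$onset + 1)
  eps <- 0.01
  disp <- .doubleGamma(t, p$peakDelay, p$peakDispersion + eps,
                       p$undershootDelay, p$undershootDispersion, p$ratio,
                       p$onset)

  new("HRFBasis", sampleTimes = t, canonical = raw / peak,
      temporalDerivative = (raw - shifted) / peak,
      dispersionDerivative = (raw - disp) / (eps * peak),
      dt = dt, duration = duration, params = p)
}

#' Construct an event train
#'
#' @param onsets event onsets in seconds from session start.
#' @param durations event durations in seconds (recycled; 0 = impulse).
#' @param spikeType label shared by all events of the train.
#' @return an [EventTrain-class]; events are sorted by onset.
#' @export
eventTrain <- function(onsets, durations = 0, spikeType = "spike") {
  onsets <- as.numeric(onsets)
  durations <- rep_len(as.numeric(durations), length(onsets))
  o <- order(onsets)
  new("EventTrain", onsets = onsets[o], durations = durations[o],
      spikeType = as.character(spikeType))
}

#' Read IED events from a BIDS-style events table
#'
#' Reads a tab-separated events file with columns `onset`, `duration` and
#' (optionally) `trial_type`, all in seconds, and returns one event train
#' per trial type.
#'
#' @param path path to the events.tsv file.
#' @return named list of [EventTrain-class] objects, one per spike type.
#' @export
readEvents <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset", "duration")
  if (!all(need %in% names(ev)))
    stop("events file must have columns 'onset' and 'duration': ", path)
  type <- if ("trial_type" %in% names(ev)) as.character(ev$trial_type)
          else rep("spike", nrow(ev))
  out <- lapply(split(seq_len(nrow(ev)), type), function(i)
    eventTrain(ev$onset[i], ev$duration[i], type[i[1]]))
  out[order(names(out))]
}

#' Write event trains to a BIDS-style events table
#'
#' @param trains list of [EventTrain-class] objects.
#' @param path output path.
#' @export
writeEvents <- function(trains, path) {
  if (is(trains, "EventTrain")) trains <- list(trains)
  df <- do.call(rbind, lapply(trains, function(tr)
    data.frame(onset = tr@onsets, duration = tr@durations,
               trial_type = rep(tr@spikeType, length(tr@onsets)))))
  df <- df[order(df$onset), , drop = FALSE]
  write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export an HRF basis as TSV
#'
#' Columns `time`, `canonical`, `temporal_derivative`,
#' `dispersion_derivative`.
#'
#' @param basis an [HRFBasis-class].
#' @param path output path.
#' @export
writeHRFBasis <- function(basis, path) {
  df <- data.frame(time = basis@sampleTimes, canonical = basis@canonical,
                   temporal_derivative = basis@temporalDerivative,
                   dispersion_derivative = basis@dispersionDerivative)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Microtime stimulus function of one train: boxcar amplitude 1 during each
# event (bins covered fractionally at the edges, so the sampled function
# converges with dt), a unit-mass impulse spread linearly over the two
# adjacent bins when duration = 0.
.stimulusFunction <- function(events, dt, nBins, sessionLen) {
  u <- numeric(nBins)
  keep <- events@onsets < sessionLen
  if (any(!keep))
    warning(sprintf("%d event(s) of type '%s' start at/after session end (%g s); ignored",
                    sum(!keep), events@spikeType, sessionLen))
  on <- events@onsets[keep]
  du <- events@durations[keep]
  addMass <- function(u, time, mass) {
    b <- floor(time / dt)
    frac <- time / dt - b
    u[b + 1L] <- u[b + 1L] + (1 - frac) * mass
    if (b + 2L <= nBins) u[b + 2L] <- u[b + 2L] + frac * mass
    u
  }
  for (k in seq_along(on)) {
    if (du[k] <= 0) {
      u <- addMass(u, on[k], 1 / dt)
    } else {
      lo <- on[k] / dt; hi <- min((on[k] + du[k]) / dt, nBins)
      b0 <- floor(lo); b1 <- min(floor(hi), nBins - 1L)
      if (b0 >= b1) {
        u[b0 + 1L] <- u[b0 + 1L] + (hi - lo)
      } else {
        u[b0 + 1L] <- u[b0 + 1L] + (b0 + 1 - lo)
        if (b1 > b0 + 1L)
          u[(b0 + 2L):b1] <- u[(b0 + 2L):b1] + 1
        u[b1 + 1L] <- u[b1 + 1L] + (hi - b1)
      }
    }
  }
  u
}

.convDownsample <- function(u, h, dt, volIdx) {
  # open (full) convolution via FFT, zero-padded to a 2-3-5-smooth length
  # (mixed-radix FFTs at awkward lengths are orders of magnitude slower);
  # scaled by dt to approximate the continuous-time integral
  n <- length(u) + length(h) - 1L
  nf <- stats::nextn(n, c(2, 3, 5))
  U <- stats::fft(c(u, numeric(nf - length(u))))
  H <- stats::fft(c(h, numeric(nf - length(h))))
  y <- Re(stats::fft(U * H, inverse = TRUE))[seq_len(n)] / nf * dt
  y[volIdx]
}

#' Event regressors at the scan repetition time
#'
#' Convolves the microtime stimulus function of an event train (boxcar for
#' events with positive duration, unit impulse for zero-duration events)
#' with each vector of the HRF basis and samples the result at the volume
#' acquisition times `t = (i - 1) * tr`. Returns three regressor columns
#' (canonical, temporal derivative, dispersion derivative) per spike type.
#'
#' @param events an [EventTrain-class] or a list of them (one per spike
#'   type).
#' @param basis an [HRFBasis-class]; its `dt` is the microtime resolution.
#' @param nVolumes number of acquired volumes.
#' @param tr repetition time in seconds.
#' @return a [DesignMatrix-class] with `3 * length(events)` columns named
#'   `<spikeType>.{canonical,temporal,dispersion}`. Events with onset at or
#'   beyond the session end are dropped with a warning; an empty train
#'   yields all-zero columns.
#' @export
buildEventRegressors <- function(events, basis, nVolumes, tr) {
  if (!is.numeric(nVolumes) || nVolumes < 1)
    stop("nVolumes must be a positive count")
  if (!is.numeric(tr) || tr <= 0) stop("tr must be positive")
  if (is(events, "EventTrain")) events <- list(events)
  stopifnot(length(events) >= 1L)

  dt <- basis@dt
  sessionLen <- nVolumes * tr
  nBins <- ceiling(sessionLen / dt) + 1L
  volIdx <- pmin(nBins, round((seq_len(nVolumes) - 1) * tr / dt) + 1L)
  H <- cbind(basis@canonical, basis@temporalDerivative,
             basis@dispersionDerivative)

  cols <- lapply(events, function(tr_k) {
    u <- .stimulusFunction(tr_k, dt, nBins, sessionLen)
    if (all(u == 0)) {
      m <- matrix(0, nVolumes, 3L)
    } else {
      m <- vapply(seq_len(3L),
                  function(j) .convDownsample(u, H[, j], dt, volIdx),
                  numeric(nVolumes))
    }
    colnames(m) <- paste0(tr_k@spikeType,
                          c(".canonical", ".temporal", ".dispersion"))
    m
  })
  new("DesignMatrix", data = do.call(cbind, cols), tr = tr)
}
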