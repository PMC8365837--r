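# Group statistics: ipsilateral AUC selection, median-difference
# permutation test, Mann-Whitney effect size, Spearman IED-burden
# correlation.

.fastMedian <- function(v) {
  n <- length(v)
  s <- sort.int(v, method = "quick")
  if (n %% 2L) s[(n + 1L) %/% 2L] else (s[n %/% 2L] + s[n %/% 2L + 1L]) / 2
}

#' Ipsilateral AUC per subject
#'
#' Implements the lateralization convention of the group comparison:
#' patients contribute the AUC of the region on the side of their
#' epileptogenic zone; controls contribute the median of the left and right
#' AUCs (the mean of the two values).
#'
#' @param aucTable data.frame with columns `subjectId`, `region`, `auc`
#'   (e.g. stacked [curveAUC()] output).
#' @param meta data.frame with columns `subjectId`, `group`
#'   ("patient"/"control") and `ezLaterality` ("left"/"right"/"none").
#' @param regionPair length-2 character: the left and right region labels.
#' @return data.frame with columns `subjectId`, `group`, `value`.
#' @export
lateralizedAUC <- function(aucTable, meta, regionPair) {
  stopifnot(length(regionPair) == 2L)
  key <- paste(aucTable$subjectId, aucTable$region, sep = "\r")
  if (anyDuplicated(key[key %in% paste(rep(meta$subjectId, each = 2L),
                                       regionPair, sep = "\r")]))
    stop("multiple AUC rows per (subject, region); filter the table first")
  lv <- aucTable$auc[match(paste(meta$subjectId, regionPair[1], sep = "\r"),
                           key)]
  rv <- aucTable$auc[match(paste(meta$subjectId, regionPair[2], sep = "\r"),
                           key)]
  if (anyNA(lv) || anyNA(rv))
    stop("missing lateralized AUC for subject(s): ",
         paste(meta$subjectId[is.na(lv) | is.na(rv)], collapse = ", "))
  isPat <- meta$group == "patient"
  bad <- isPat & !meta$ezLaterality %in% c("left", "right")
  if (any(bad))
    stop("patient(s) without EZ laterality: ",
         paste(meta$subjectId[bad], collapse = ", "))
  value <- ifelse(isPat, ifelse(meta$ezLaterality == "left", lv, rv),
                  (lv + rv) / 2)
  data.frame(subjectId = meta$subjectId, group = meta$group, value = value,
             stringsAsFactors = FALSE)
}

#' Mann-Whitney effect size r = z / sqrt(n1 + n2)
#'
#' Computes the Mann-Whitney U statistic, its tie-corrected
#' normal-approximation z (no continuity correction), and the standardized
#' effect size r.
#'
#' @param x,y numeric value vectors of the two groups.
#' @return list with elements `U`, `z`, `r`, `n1`, `n2`.
#' @export
mannWhitneyR <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n == 0L) stop("no data")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  tieTab <- table(r)
  tieCorr <- sum(tieTab^3 - tieTab) / (n * (n - 1))
  s2 <- n1 * n2 / 12 * ((n + 1) - tieCorr)
  z <- if (s2 > 0) (U - mu) / sqrt(s2) else 0
  list(U = U, z = z, r = max(-1, min(1, z / sqrt(n))), n1 = n1, n2 = n2)
}

.permPValue <- function(tNull, tObs, denomPlusOne) {
  tol <- 1e-12 * max(1, abs(tObs))
  hits <- sum(abs(tNull) >= abs(tObs) - tol)
  if (denomPlusOne) (1 + hits) / (length(tNull) + 1) else hits / length(tNull)
}

#' Permutation test on the difference of group medians
#'
#' Statistic `T = median(x) - median(y)`; the null distribution is built by
#' re-assigning the pooled values to groups of sizes n1 and n2. The
#' two-tailed Monte-Carlo p-value is `(1 + #{|T_perm| >= |T_obs|}) /
#' (nPerm + 1)`. For `n1 + n2 <= 12` (or on request) all
#' `choose(n1 + n2, n1)` assignments are enumerated instead and the p-value
#' is the exact tail proportion. The Mann-Whitney effect size
#' \eqn{r = z / \sqrt{n_1 + n_2}} is attached.
#'
#' @param x,y numeric value vectors (patients and controls), length >= 2
#'   each.
#' @param nPerm number of Monte-Carlo permutations (default 10000).
#' @param seed optional RNG seed for the permutation draw.
#' @param exhaustive force (TRUE) or forbid (FALSE) full enumeration;
#'   default NULL enumerates when `n1 + n2 <= 12`.
#' @param region,metric labels carried into the result.
#' @return a [GroupComparison-class].
#' @export
permutationMedianTest <- function(x, y, nPerm = 10000, seed = NULL,
                                  exhaustive = NULL, region = "",
                                  metric = "") {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n1 < 2L || n2 < 2L) stop("need at least 2 values per group")
  if (nPerm < 1) stop("nPerm must be >= 1")
  pool <- c(x, y)
  tObs <- .fastMedian(x) - .fastMedian(y)
  if (is.null(exhaustive)) exhaustive <- n <= 12L
  if (!is.null(seed)) set.seed(seed)

  if (exhaustive) {
    comb <- utils::combn(n, n1)
    tNull <- vapply(seq_len(ncol(comb)), function(k) {
      .fastMedian(pool[comb[, k]]) - .fastMedian(pool[-comb[, k]])
    }, numeric(1))
    p <- .permPValue(tNull, tObs, denomPlusOne = FALSE)
    nP <- ncol(comb); method <- "exhaustive"
  } else {
    tNull <- vapply(seq_len(nPerm), function(k) {
      idx <- sample.int(n, n1)
      .fastMedian(pool[idx]) - .fastMedian(pool[-idx])
    }, numeric(1))
    p <- .permPValue(tNull, tObs, denomPlusOne = TRUE)
    nP <- nPerm; method <- "monte-carlo"
  }
  es <- mannWhitneyR(x, y)
  new("GroupComparison", region = region, metric = metric,
      observedDiff = tObs, pValue = p, effectSizeR = es$r,
      nPermutations = as.numeric(nP), n1 = as.integer(n1),
      n2 = as.integer(n2), method = method)
}

#' Compare AUC before vs after IED correction
#'
#' Applies the same permutation machinery as the patient-vs-control test to
#' the two condition-wise value sets (default: unpaired label permutation,
#' mirroring the group test). Since the two conditions contain the same
#' subjects, a paired sign-flip permutation on the within-subject
#' differences is available via `paired = TRUE`.
#'
#' @param aucBefore,aucAfter per-subject AUC values before and after the
#'   IED correction, in the same subject order.
#' @param nPerm number of permutations.
#' @param seed optional RNG seed.
#' @param paired use the sign-flip variant (default FALSE).
#' @param region,metric labels carried into the result.
#' @return a [GroupComparison-class].
#' @export
compareBeforeAfterIED <- function(aucBefore, aucAfter, nPerm = 10000,
                                  seed = NULL, paired = FALSE, region = "",
                                  metric = "") {
  if (length(aucBefore) != length(aucAfter))
    stop("before/after must contain the same subjects")
  if (!paired)
    return(permutationMedianTest(aucBefore, aucAfter, nPerm = nPerm,
                                 seed = seed, region = region,
                                 metric = metric))
  d <- aucAfter - aucBefore
  n <- length(d)
  tObs <- .fastMedian(d)
  if (!is.null(seed)) set.seed(seed)
  if (n <= 12L) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    tNull <- apply(signs, 1L, function(s) .fastMedian(s * d))
    p <- .permPValue(tNull, tObs, denomPlusOne = FALSE)
    nP <- nrow(signs); method <- "sign-flip"
  } else {
    tNull <- vapply(seq_len(nPerm), function(k) {
      .fastMedian(sample(c(-1, 1), n, replace = TRUE) * d)
    }, numeric(1))
    p <- .permPValue(tNull, tObs, denomPlusOne = TRUE)
    nP <- nPerm; method <- "sign-flip"
  }
  es <- mannWhitneyR(aucBefore, aucAfter)
  new("GroupComparison", region = region, metric = metric,
      observedDiff = tObs, pValue = p, effectSizeR = es$r,
      nPermutations = as.numeric(nP), n1 = as.integer(n),
      n2 = as.integer(n), method = method)
}

#' Spearman correlation of AUC against IED burden
#'
#' Spearman rank correlation (tie-corrected midranks) between per-patient
#' AUC values and per-session spike counts, with a two-tailed p-value from
#' the t approximation.
#'
#' @param aucValues,spikeCounts paired numeric vectors, length >= 3.
#' @return list with elements `rho`, `p`, `n`.
#' @export
spearmanAUCSpikes <- function(aucValues, spikeCounts) {
  n <- length(aucValues)
  if (length(spikeCounts) != n) stop("vectors must be paired")
  if (n < 3L) stop("need at least 3 pairs")
  if (stats::sd(aucValues) == 0 || stats::sd(spikeCounts) == 0)
    stop("Spearman correlation undefined for a constant vector")
  rho <- stats::cor(rank(aucValues), rank(spikeCounts))
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Flatten GroupComparison objects into a results table
#'
#' @param comparisons a [GroupComparison-class] or list of them.
#' @return data.frame with columns `region`, `metric`, `n1`, `n2`,
#'   `observedDiff`, `p`, `r`, `nPerm`, `method`.
#' @export
comparisonTable <- function(comparisons) {
  if (is(comparisons, "GroupComparison")) comparisons <- list(comparisons)
  do.call(rbind, lapply(comparisons, function(gc)
    data.frame(region = gc@region, metric = gc@metric, n1 = gc@n1,
               n2 = gc@n2, observedDiff = gc@observedDiff, p = gc@pValue,
               r = gc@effectSizeR, nPerm = gc@nPermutations,
               method = gc@method, stringsAsFactors = FALSE)))
}
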