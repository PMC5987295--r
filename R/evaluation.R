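# Biometric performance evaluation: Hamming-distance score sets, FAR/FRR
# curves, EER, CCR, ROC/AUC, identification (all-subjects) and verification
# (one-vs-rest) scenarios, McNemar test with Yates correction, and Fisher-Z
# pooling of accuracies. Acceptance convention throughout: a probe is
# accepted iff its normalized distance is <= the threshold, so FAR is
# non-decreasing and FRR non-increasing in the threshold.

#' Normalized Hamming distance between two codes
#'
#' Fraction of differing bit positions, (1/n) sum_i a_i XOR b_i.
#'
#' @param codeA,codeB \linkS4class{EEGCode}s or 0/1 bit vectors of equal
#'   length.
#' @param raw if TRUE return the raw differing-bit count instead.
#' @return normalized distance in [0, 1] (or an integer count).
#' @export
hammingDistance <- function(codeA, codeB, raw = FALSE) {
  a <- if (is(codeA, "EEGCode")) codeBits(codeA) else as.integer(codeA)
  b <- if (is(codeB, "EEGCode")) codeBits(codeB) else as.integer(codeB)
  if (length(a) != length(b)) stop("codes differ in length")
  d <- sum(a != b)
  if (raw) as.integer(d) else d / length(a)
}

#' Encode every recording of a cohort
#' @param cohort an \linkS4class{EEGCohort}.
#' @return list of \linkS4class{EEGCode}.
#' @export
encodeCohort <- function(cohort) lapply(recordings(cohort), encodeEEG)

#' Genuine and impostor score set of a cohort
#'
#' All unordered same-subject pairs contribute genuine scores; all
#' cross-subject pairs contribute impostor scores.
#'
#' @param codes list of \linkS4class{EEGCode} (or 0/1 bit vectors), or an
#'   \linkS4class{EEGCohort} (encoded on the fly).
#' @param subjectIds character vector parallel to codes (ignored when a
#'   cohort is given).
#' @return a \linkS4class{ScoreSet}.
#' @export
scoreCohort <- function(codes, subjectIds = NULL) {
  if (is(codes, "EEGCohort")) {
    subjectIds <- subjectIds(codes)
    codes <- encodeCohort(codes)
  }
  bits <- lapply(codes, function(cd) if (is(cd, "EEGCode")) codeBits(cd) else as.integer(cd))
  n <- length(bits)
  if (n < 2 || length(unique(subjectIds)) < 2)
    stop("at least 2 subjects are required")
  len <- length(bits[[1]])
  M <- do.call(rbind, bits)
  gBits <- integer(0); iBits <- integer(0)
  for (i in seq_len(n - 1)) {
    d <- as.integer(rowSums(M[(i + 1):n, , drop = FALSE] !=
                            matrix(M[i, ], n - i, len, byrow = TRUE)))
    same <- subjectIds[(i + 1):n] == subjectIds[i]
    gBits <- c(gBits, d[same]); iBits <- c(iBits, d[!same])
  }
  if (length(gBits) == 0)
    stop("no genuine pairs: some subject needs at least 2 samples")
  new("ScoreSet", genuine = gBits / len, impostor = iBits / len,
      genuineBits = gBits, impostorBits = iBits, codeLength = as.integer(len))
}

#' Threshold grid for a score set
#'
#' All distinct observed scores plus the endpoints 0 and 1, giving exact
#' step-function evaluation of the FAR/FRR curves without binning error.
#'
#' @param scores a \linkS4class{ScoreSet}.
#' @return sorted numeric vector.
#' @export
thresholdGrid <- function(scores) {
  sort(unique(c(0, scores@genuine, scores@impostor, 1)))
}

#' FAR and FRR curves over a threshold grid
#'
#' Accept iff distance <= threshold: FAR(T) is the fraction of impostor
#' scores accepted, FRR(T) the fraction of genuine scores rejected.
#'
#' @param scores a \linkS4class{ScoreSet}.
#' @param thresholds numeric grid (defaults to \code{thresholdGrid}).
#' @return data.frame with columns threshold, far, frr.
#' @export
farFrr <- function(scores, thresholds = thresholdGrid(scores)) {
  if (length(thresholds) == 0) stop("empty threshold grid")
  if (length(scores@genuine) == 0 || length(scores@impostor) == 0)
    stop("both genuine and impostor scores are required")
  far <- vapply(thresholds, function(T) mean(scores@impostor <= T), numeric(1))
  frr <- vapply(thresholds, function(T) mean(scores@genuine > T), numeric(1))
  data.frame(threshold = thresholds, far = far, frr = frr)
}

#' Equal error rate
#'
#' The operating threshold T* minimizes |FAR(T) - FRR(T)| over the grid (ties
#' broken toward the smallest threshold); the reported EER is the midpoint
#' (FAR(T*) + FRR(T*)) / 2, since exact equality rarely occurs on a finite
#' grid.
#'
#' @param scores a \linkS4class{ScoreSet}, or a data.frame from
#'   \code{\link{farFrr}}.
#' @param thresholds optional grid when a ScoreSet is given.
#' @return list with eer and threshold.
#' @export
eer <- function(scores, thresholds = NULL) {
  curves <- if (is(scores, "ScoreSet")) {
    if (is.null(thresholds)) farFrr(scores) else farFrr(scores, thresholds)
  } else scores
  i <- which.min(abs(curves$far - curves$frr))
  list(eer = (curves$far[i] + curves$frr[i]) / 2,
       threshold = curves$threshold[i])
}

#' Correct classification rate
#' @param decisions vector of decisions.
#' @param truths vector of ground-truth labels, same length.
#' @return fraction of correct decisions.
#' @export
ccr <- function(decisions, truths) {
  if (length(decisions) != length(truths)) stop("length mismatch")
  if (length(decisions) == 0) stop("no trials")
  mean(decisions == truths)
}

#' Area under the ROC curve
#'
#' Trapezoidal area under TPR versus FPR swept over all distinct score
#' thresholds (acceptance at distance <= T). On step-function data this
#' equals the normalized Mann-Whitney U statistic with the half-tie
#' convention.
#'
#' @param scores a \linkS4class{ScoreSet}.
#' @return area in [0, 1]; 1 means genuine scores are all below impostor
#'   scores.
#' @export
rocAuc <- function(scores) {
  g <- scores@genuine; im <- scores@impostor
  if (length(g) == 0 || length(im) == 0) stop("both score lists are required")
  ts <- sort(unique(c(g, im)))
  tpr <- vapply(ts, function(T) mean(g <= T), numeric(1))
  fpr <- vapply(ts, function(T) mean(im <= T), numeric(1))
  xs <- c(0, fpr, 1); ys <- c(0, tpr, 1)
  sum(diff(xs) * (head(ys, -1) + ys[-1]) / 2)
}

#' Identification scenario: classify every probe among all subjects
#'
#' Leave-one-out nearest-template classification by normalized Hamming
#' distance: each recording's code is matched against every other recording's
#' code and assigned the subject of the nearest one (ties broken toward the
#' lowest subject index). Subjects with a single sample are excluded with a
#' warning (they cannot be probed leave-one-out).
#'
#' @param codes list of \linkS4class{EEGCode} / bit vectors, or an
#'   \linkS4class{EEGCohort}.
#' @param subjectIds character vector parallel to codes.
#' @return list with perSubjectCCR, meanCCR, confusion (S x S count matrix,
#'   rows = true subject, columns = predicted).
#' @export
scenario1 <- function(codes, subjectIds = NULL) {
  if (is(codes, "EEGCohort")) {
    subjectIds <- subjectIds(codes); codes <- encodeCohort(codes)
  }
  bits <- lapply(codes, function(cd) if (is(cd, "EEGCode")) codeBits(cd) else as.integer(cd))
  counts <- table(subjectIds)
  single <- names(counts)[counts < 2]
  if (length(single) > 0) {
    warning("excluding subjects with a single sample: ",
            paste(single, collapse = ", "))
    keep <- !(subjectIds %in% single)
    bits <- bits[keep]; subjectIds <- subjectIds[keep]
  }
  subjects <- sort(unique(subjectIds))
  if (length(subjects) < 2) stop("at least 2 subjects with 2+ samples needed")
  M <- do.call(rbind, bits)
  n <- nrow(M)
  D <- as.matrix(dist(M, method = "manhattan")) / ncol(M)
  diag(D) <- Inf
  predicted <- character(n)
  for (i in seq_len(n)) {
    j <- which(D[i, ] == min(D[i, ]))
    # tie-break toward the lowest subject index
    predicted[i] <- sort(subjectIds[j])[1]
  }
  confusion <- table(factor(subjectIds, levels = subjects),
                     factor(predicted, levels = subjects))
  perSubject <- vapply(subjects, function(s) {
    mean(predicted[subjectIds == s] == s)
  }, numeric(1))
  list(perSubjectCCR = perSubject, meanCCR = mean(predicted == subjectIds),
       confusion = unclass(confusion))
}

#' Verification scenario: one subject versus the rest
#'
#' The samples are split into enrolment and probe halves per subject (seeded).
#' The acceptance threshold is the EER threshold of the enrolment-half score
#' set (target-vs-target genuine, target-vs-others impostor). Each probe is
#' scored by its minimum distance to the target's enrolment codes; positive
#' probes are bootstrap-oversampled (seeded) so both classes are balanced;
#' accept iff score <= threshold.
#'
#' @param codes list of codes or an \linkS4class{EEGCohort}.
#' @param subjectIds character vector parallel to codes.
#' @param target subject id of the positive class.
#' @param seed integer seed for the split and the bootstrap.
#' @return list with confusion (2 x 2: rows truth, cols decision), tpr,
#'   threshold.
#' @export
scenario2 <- function(codes, subjectIds = NULL, target, seed = 1) {
  if (is(codes, "EEGCohort")) {
    subjectIds <- subjectIds(codes); codes <- encodeCohort(codes)
  }
  bits <- lapply(codes, function(cd) if (is(cd, "EEGCode")) codeBits(cd) else as.integer(cd))
  if (!(target %in% subjectIds)) stop("target subject not present")
  .withSeed(seed, {
    n <- length(bits)
    enrolHalf <- logical(n)
    for (s in unique(subjectIds)) {
      idx <- which(subjectIds == s)
      take <- sample(idx, ceiling(length(idx) / 2))
      enrolHalf[take] <- TRUE
    }
    if (sum(enrolHalf & subjectIds == target) < 2)
      stop("target needs at least 2 enrolment samples for a genuine score")
    refIdx <- which(enrolHalf & subjectIds == target)
    othIdx <- which(enrolHalf & subjectIds != target)
    gtrain <- unlist(lapply(combn(refIdx, 2, simplify = FALSE), function(pr) {
      hammingDistance(bits[[pr[1]]], bits[[pr[2]]])
    }))
    itrain <- unlist(lapply(othIdx, function(i) {
      min(vapply(refIdx, function(r) hammingDistance(bits[[i]], bits[[r]]),
                 numeric(1)))
    }))
    ss <- new("ScoreSet", genuine = gtrain, impostor = itrain,
              genuineBits = as.integer(round(gtrain * length(bits[[1]]))),
              impostorBits = as.integer(round(itrain * length(bits[[1]]))),
              codeLength = length(bits[[1]]))
    # operating point: the EER threshold sits exactly on an observed training
    # score (step-function grid), so shift to the midpoint of the gap up to
    # the next grid value -- otherwise boundary probes split arbitrarily
    grid <- thresholdGrid(ss)
    tstar <- eer(ss, thresholds = grid)$threshold
    above <- grid[grid > tstar]
    thr <- if (length(above)) (tstar + min(above)) / 2 else tstar
    probeIdx <- which(!enrolHalf)
    pos <- probeIdx[subjectIds[probeIdx] == target]
    neg <- probeIdx[subjectIds[probeIdx] != target]
    if (length(pos) == 0) stop("no positive probes left after the split")
    posBal <- sample(pos, length(neg), replace = TRUE)
    probes <- c(posBal, neg)
    truth <- c(rep(TRUE, length(posBal)), rep(FALSE, length(neg)))
    score <- vapply(probes, function(i) {
      min(vapply(refIdx, function(r) hammingDistance(bits[[i]], bits[[r]]),
                 numeric(1)))
    }, numeric(1))
    accept <- score <= thr
    confusion <- matrix(c(sum(truth & accept), sum(truth & !accept),
                          sum(!truth & accept), sum(!truth & !accept)),
                        2, 2, byrow = TRUE,
                        dimnames = list(truth = c("target", "other"),
                                        decision = c("accept", "reject")))
    list(confusion = confusion, tpr = mean(accept[truth]), threshold = thr)
  })
}

#' McNemar chi-square statistic with Yates correction
#'
#' (|b - c| - 1)^2 / (b + c) on the discordant counts, defined as 0 when
#' b + c = 0; compare against the df = 1 critical value
#' (\code{qchisq(0.95, 1)}, about 3.8415, at the 95% level).
#'
#' @param b,c discordant pair counts (nonnegative).
#' @return list with statistic, criticalValue95, significant.
#' @export
mcnemarYates <- function(b, c) {
  if (b < 0 || c < 0) stop("counts must be nonnegative")
  stat <- if (b + c == 0) 0 else (abs(b - c) - 1)^2 / (b + c)
  crit <- qchisq(0.95, df = 1)
  list(statistic = stat, criticalValue95 = crit, significant = stat > crit)
}

#' Fisher-Z pooled mean and spread of accuracies
#'
#' Applies atanh to each accuracy (treated as if a correlation, clipped into
#' (-1 + 1e-6, 1 - 1e-6)), averages in the transformed space, and
#' back-transforms the mean with tanh. The sd is reported in the transformed
#' space.
#'
#' @param accuracies numeric vector of rates in [0, 1].
#' @return list with mean (back-transformed), sd (transformed space).
#' @export
fisherZMean <- function(accuracies) {
  if (length(accuracies) == 0) stop("empty accuracy list")
  if (any(accuracies < 0 | accuracies > 1)) stop("accuracies must be in [0, 1]")
  eps <- 1e-6
  z <- atanh(pmin(pmax(accuracies, -1 + eps), 1 - eps))
  list(mean = tanh(mean(z)), sd = if (length(z) > 1) sd(z) else 0)
}

#' Empirical error-tolerance crossing point
#'
#' Builds per-bit-count histograms (n + 1 bins, normalized to densities) of
#' the genuine and impostor raw distances and returns the largest bit count d
#' such that the genuine density is at least the impostor density at every
#' count <= d -- the empirical crossing of the two distributions, i.e. the
#' number of bit errors the genuine population can claim before impostors
#' dominate.
#'
#' @param scores a \linkS4class{ScoreSet} (raw bit counts are used).
#' @return integer in [0, n].
#' @export
errorToleranceBits <- function(scores) {
  if (length(scores@genuineBits) == 0 || length(scores@impostorBits) == 0)
    stop("both score lists are required")
  n <- scores@codeLength
  gd <- tabulate(scores@genuineBits + 1L, nbins = n + 1L) /
    length(scores@genuineBits)
  id <- tabulate(scores@impostorBits + 1L, nbins = n + 1L) /
    length(scores@impostorBits)
  ok <- gd >= id
  if (!ok[1]) return(0L)
  d <- which(!ok)[1]
  if (is.na(d)) n else as.integer(d - 2L)
}

#' Write an evaluation report to disk
#'
#' Curves as CSV (threshold, FAR, FRR) and scalars as JSON (EER and its
#' threshold, AUC, mean CCR, error-tolerance bits).
#'
#' @param scores a \linkS4class{ScoreSet}.
#' @param dir output directory.
#' @param scen1 optional result of \code{\link{scenario1}} to include.
#' @return paths of the written files, invisibly.
#' @export
writeEvalReport <- function(scores, dir, scen1 = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  curves <- farFrr(scores)
  cpath <- file.path(dir, "far_frr.csv")
  write.csv(curves, cpath, row.names = FALSE)
  e <- eer(scores)
  scalars <- list(eer = e$eer, eer_threshold = e$threshold,
                  auc = rocAuc(scores),
                  error_tolerance_bits = errorToleranceBits(scores))
  if (!is.null(scen1)) scalars$mean_ccr <- scen1$meanCCR
  jpath <- file.path(dir, "summary.json")
  jsonlite::write_json(scalars, jpath, auto_unbox = TRUE, digits = NA)
  invisible(c(cpath, jpath))
}
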