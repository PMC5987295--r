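# Synthetic multi-subject EEG cohorts. Each subject is a stable spatial
# covariance (random factor model A A'/C + ridge); a recording is a zero-mean
# Gaussian draw whose covariance is the base perturbed by seeded symmetric
# session noise and projected back to positive-definite. The construction
# targets the property the pipeline consumes: binary codes of the same
# subject are close in Hamming distance, codes of different subjects far.

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Create a synthetic subject model
#'
#' Builds a reproducible per-subject base covariance from a random factor
#' model: A A' / channels + 0.05 I with A a channels x channels standard
#' normal matrix drawn under the seed. The ridge guarantees positive
#' definiteness; the random factors give each subject a distinct binarized
#' covariance pattern.
#'
#' @param nChannels number of channels (>= 2).
#' @param seed integer seed; the model is a pure function of
#'   (nChannels, seed).
#' @param subjectId optional identifier (defaults to "S<seed>").
#' @return a \linkS4class{SubjectModel}.
#' @export
makeSubject <- function(nChannels, seed, subjectId = NULL) {
  if (nChannels < 2) stop("nChannels must be at least 2")
  nChannels <- as.integer(nChannels)
  if (is.null(subjectId)) subjectId <- paste0("S", seed)
  B <- .withSeed(seed, {
    A <- matrix(rnorm(nChannels * nChannels), nChannels, nChannels)
    tcrossprod(A) / nChannels + diag(0.05, nChannels)
  })
  new("SubjectModel", subjectId = as.character(subjectId),
      baseCovariance = B, seed = as.integer(seed))
}

# symmetric eigenvalue clip at a small positive floor
.projectPD <- function(M, floor = 1e-6) {
  es <- eigen((M + t(M)) / 2, symmetric = TRUE)
  lam <- pmax(es$values, floor)
  es$vectors %*% (lam * t(es$vectors))
}

#' Draw a recording from a subject model
#'
#' The session covariance is base + sessionNoise * (G + G')/2 with G a seeded
#' standard normal matrix, eigenvalue-clipped at 1e-6 to stay
#' positive-definite; the recording is a zero-mean multivariate normal sample
#' with that covariance. sessionNoise = 0 reproduces the base covariance
#' parameter exactly.
#'
#' @param subject a \linkS4class{SubjectModel}.
#' @param nTimepoints number of time samples (>= 1).
#' @param sessionNoise nonnegative scalar; scale of the symmetric covariance
#'   perturbation (the base has unit-scale diagonal).
#' @param seed integer seed; same (subject, seed) gives an identical
#'   recording.
#' @param samplingRate attached sampling rate in Hz.
#' @return an \linkS4class{EEGRecording}.
#' @export
sampleRecording <- function(subject, nTimepoints = 1000, sessionNoise = 0.1,
                            seed = 1, samplingRate = 256) {
  if (nTimepoints < 1) stop("nTimepoints must be at least 1")
  if (sessionNoise < 0) stop("sessionNoise must be nonnegative")
  C <- nrow(subject@baseCovariance)
  X <- .withSeed(seed, {
    S <- subject@baseCovariance
    if (sessionNoise > 0) {
      G <- matrix(rnorm(C * C), C, C)
      S <- .projectPD(S + sessionNoise * (G + t(G)) / 2)
    }
    t(MASS::mvrnorm(n = nTimepoints, mu = rep(0, C), Sigma = S))
  })
  eegRecording(X, samplingRate = samplingRate)
}

#' Cohort configuration
#'
#' Defaults mirror the emulated study scale: 20 channels, 1000 time samples
#' per recording at 256 Hz. Per-subject sample counts are uniform;
#' \code{samplesPerSubject} may be a vector (one count per subject) to
#' override the allocation.
#'
#' @param nSubjects number of subjects.
#' @param samplesPerSubject recordings per subject (scalar or vector).
#' @param nChannels channels (>= 2, default 20).
#' @param nTimepoints samples per recording (> nChannels, default 1000).
#' @param samplingRate Hz (default 256).
#' @param sessionNoise within-subject covariance perturbation scale
#'   (default 0.1).
#' @param masterSeed integer; the whole cohort is a pure function of the
#'   configuration including this seed.
#' @return a list of class "CohortConfig".
#' @export
cohortConfig <- function(nSubjects, samplesPerSubject, nChannels = 20,
                         nTimepoints = 1000, samplingRate = 256,
                         sessionNoise = 0.1, masterSeed = 1) {
  if (nChannels < 2) stop("nChannels must be at least 2")
  if (nTimepoints <= nChannels) stop("nTimepoints must exceed nChannels")
  if (sessionNoise < 0) stop("sessionNoise must be nonnegative")
  spc <- rep_len(as.integer(samplesPerSubject), nSubjects)
  structure(list(nSubjects = as.integer(nSubjects), samplesPerSubject = spc,
                 nChannels = as.integer(nChannels),
                 nTimepoints = as.integer(nTimepoints),
                 samplingRate = as.numeric(samplingRate),
                 sessionNoise = as.numeric(sessionNoise),
                 masterSeed = as.integer(masterSeed)),
            class = "CohortConfig")
}

#' Generate a synthetic cohort
#'
#' Produces sum(samplesPerSubject) recordings across nSubjects subjects,
#' deterministically under the master seed: per-subject model seeds and
#' per-recording session seeds are drawn once from the master-seeded stream.
#'
#' @param config a configuration from \code{\link{cohortConfig}}.
#' @return an \linkS4class{EEGCohort}.
#' @examples
#' coh <- makeCohort(cohortConfig(3, 2, nChannels = 5, nTimepoints = 50))
#' length(recordings(coh)) # 6
#' @export
makeCohort <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  total <- sum(config$samplesPerSubject)
  seeds <- .withSeed(config$masterSeed, {
    list(subject = sample.int(.Machine$integer.max, config$nSubjects),
         session = sample.int(.Machine$integer.max, total))
  })
  recs <- vector("list", total)
  ids <- character(total)
  idx <- 0L
  for (s in seq_len(config$nSubjects)) {
    subj <- makeSubject(config$nChannels, seeds$subject[s],
                        subjectId = sprintf("S%02d", s))
    for (r in seq_len(config$samplesPerSubject[s])) {
      idx <- idx + 1L
      recs[[idx]] <- sampleRecording(subj, config$nTimepoints,
                                     config$sessionNoise,
                                     seed = seeds$session[idx],
                                     samplingRate = config$samplingRate)
      ids[idx] <- subj@subjectId
    }
  }
  new("EEGCohort", recordings = recs, subjectIds = ids,
      config = unclass(config))
}

#' Write a cohort to disk as CSV files
#'
#' One CSV per recording (see \code{\link{writeRecordingCSV}}) plus a
#' manifest CSV with columns file, subject_id, seed.
#'
#' @param cohort an \linkS4class{EEGCohort}.
#' @param dir output directory (created if needed).
#' @return path of the manifest file, invisibly.
#' @export
writeCohortCSV <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(cohort@recordings)
  files <- sprintf("rec%03d.csv", seq_len(n))
  for (i in seq_len(n))
    writeRecordingCSV(cohort@recordings[[i]], file.path(dir, files[i]))
  manifest <- data.frame(file = files, subject_id = cohort@subjectIds,
                         seed = cohort@config$masterSeed)
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a cohort written by \code{writeCohortCSV}
#'
#' @param dir directory containing manifest.csv and per-recording CSVs.
#' @param samplingRate sampling rate to attach (Hz).
#' @return an \linkS4class{EEGCohort}.
#' @export
readCohortCSV <- function(dir, samplingRate = 256) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stop("no manifest.csv in ", dir)
  manifest <- read.csv(mpath)
  recs <- lapply(file.path(dir, manifest$file), readRecordingCSV,
                 samplingRate = samplingRate)
  new("EEGCohort", recordings = recs,
      subjectIds = as.character(manifest$subject_id),
      config = list(masterSeed = manifest$seed[1]))
}
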