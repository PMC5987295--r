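# EEG encoding: recording -> covariance -> column z-scores -> min-max
# normalization -> 0.5 thresholding -> row-major bit vector. For a 20-channel
# recording the result is the 400-bit EEG code.

#' Construct an EEG recording object
#'
#' @param data numeric matrix, channels in rows and time samples in columns.
#' @param channelLabels optional channel labels (defaults to a 10-20 layout
#'   for 20 channels, generic labels otherwise).
#' @param samplingRate sampling rate in Hz (default 256).
#' @return an \linkS4class{EEGRecording}.
#' @export
eegRecording <- function(data, channelLabels = NULL, samplingRate = 256) {
  data <- as.matrix(data)
  dimnames(data) <- NULL
  if (is.null(channelLabels)) channelLabels <- defaultChannelLabels(nrow(data))
  new("EEGRecording", data = data, channelLabels = as.character(channelLabels),
      samplingRate = as.numeric(samplingRate))
}

#' Standard channel labels
#'
#' For 20 channels, the 10-20 international layout (Fp1 ... O2); for other
#' counts, generic "ch1" ... labels.
#'
#' @param n number of channels.
#' @return character vector of length n.
#' @export
defaultChannelLabels <- function(n) {
  layout20 <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
                "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "Oz", "O2")
  if (n == 20L) layout20 else paste0("ch", seq_len(n))
}

#' Channel covariance matrix of a recording
#'
#' Entry (i, j) is the average over the T time samples of the product of the
#' mean-centered signals of channels i and j (population form, divisor T).
#' The output is symmetric, channels x channels.
#'
#' @param rec an \linkS4class{EEGRecording} or a channels x samples matrix.
#' @return symmetric numeric matrix.
#' @export
covarianceMatrix <- function(rec) {
  X <- if (is(rec, "EEGRecording")) eegData(rec) else as.matrix(rec)
  if (ncol(X) < 2) stop("at least 2 time samples per channel are required")
  Xc <- X - rowMeans(X)
  tcrossprod(Xc) / ncol(X)
}

#' Column-wise z-scores of a square matrix
#'
#' Each column is centered by its mean and scaled by its sample standard
#' deviation (divisor N - 1). A zero-variance column is mapped to all zeros
#' rather than dividing by zero.
#'
#' @param cov square numeric matrix (N >= 2 rows).
#' @return numeric matrix of the same shape.
#' @export
zscoreColumns <- function(cov) {
  cov <- as.matrix(cov)
  if (nrow(cov) != ncol(cov)) stop("input must be a square matrix")
  if (nrow(cov) < 2) stop("at least 2 rows are required")
  mu <- colMeans(cov)
  sdv <- apply(cov, 2, sd)
  Z <- sweep(cov, 2, mu, "-")
  zero <- sdv == 0
  sdv[zero] <- 1
  Z <- sweep(Z, 2, sdv, "/")
  Z[, zero] <- 0
  Z
}

#' Global min-max normalization into [0, 1]
#'
#' (Z - min Z) / (max Z - min Z), with min and max taken over the whole
#' matrix. A constant matrix maps to all zeros.
#'
#' @param z numeric matrix.
#' @return numeric matrix with values in [0, 1].
#' @export
minmaxNormalize <- function(z) {
  z <- as.matrix(z)
  if (length(z) == 0) stop("empty matrix")
  lo <- min(z); hi <- max(z)
  if (hi == lo) return(array(0, dim = dim(z)))
  (z - lo) / (hi - lo)
}

#' Threshold a [0, 1] matrix at 0.5
#'
#' Entries >= 0.5 become 1, entries below become 0.
#'
#' @param znorm numeric matrix with all entries in [0, 1].
#' @return integer 0/1 matrix.
#' @export
binarizeMatrix <- function(znorm) {
  znorm <- as.matrix(znorm)
  if (any(znorm < 0 | znorm > 1)) stop("entries must lie in [0, 1]")
  array((znorm >= 0.5) * 1L, dim = dim(znorm))
}

#' Encode a recording into its binary EEG code
#'
#' Composition of \code{covarianceMatrix}, \code{zscoreColumns},
#' \code{minmaxNormalize} and \code{binarizeMatrix}; the binary matrix is
#' flattened row-major into a bit vector of length channels^2 (400 bits for
#' 20 channels). The pipeline is deterministic and invariant to multiplying
#' all channels by a common positive constant.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @return an \linkS4class{EEGCode}.
#' @examples
#' set.seed(1)
#' rec <- eegRecording(matrix(rnorm(20 * 100), nrow = 20))
#' code <- encodeEEG(rec)
#' length(codeBits(code)) # 400
#' @export
encodeEEG <- function(rec) {
  stopifnot(is(rec, "EEGRecording"))
  B <- binarizeMatrix(minmaxNormalize(zscoreColumns(covarianceMatrix(rec))))
  new("EEGCode", bits = as.integer(t(B)), sourceChannels = nrow(eegData(rec)))
}

#' Read / write a recording as CSV
#'
#' The CSV layout is one row per channel: a first column \code{channel} with
#' the label, then one column per time sample. Channel order is taken from
#' file order.
#'
#' @param path file path.
#' @param samplingRate sampling rate to attach on read (Hz).
#' @return \code{readRecordingCSV} returns an \linkS4class{EEGRecording}.
#' @export
readRecordingCSV <- function(path, samplingRate = 256) {
  df <- read.csv(path, check.names = FALSE)
  if (ncol(df) < 3 || names(df)[1] != "channel")
    stop("malformed recording CSV (expected a 'channel' column then samples): ",
         path)
  M <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(M)) stop("non-numeric sample values in ", path)
  dimnames(M) <- NULL
  eegRecording(M, channelLabels = as.character(df[[1]]),
               samplingRate = samplingRate)
}

#' @rdname readRecordingCSV
#' @param rec an \linkS4class{EEGRecording}.
#' @export
writeRecordingCSV <- function(rec, path) {
  X <- eegData(rec)
  df <- data.frame(channel = channelLabels(rec), X, check.names = FALSE)
  names(df) <- c("channel", paste0("s", seq_len(ncol(X))))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
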