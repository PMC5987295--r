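#' Multichannel EEG recording
#'
#' A real-valued matrix of channels x time samples with channel labels and a
#' sampling rate. Units (typically microvolts) are irrelevant to the encoding
#' pipeline, which is invariant to uniform positive rescaling.
#'
#' @slot data numeric matrix, channels in rows, time samples in columns.
#' @slot channelLabels character vector, one label per channel.
#' @slot samplingRate sampling rate in Hz.
#' @exportClass EEGRecording
setClass("EEGRecording",
  representation(data = "matrix", channelLabels = "character",
                 samplingRate = "numeric"),
  validity = function(object) {
    d <- object@data
    if (!is.numeric(d)) return("data must be a numeric matrix")
    if (nrow(d) < 2) return("recording needs at least 2 channels")
    if (ncol(d) < 2) return("recording needs at least 2 time samples")
    if (anyNA(d)) return("recording contains missing values")
    if (length(object@channelLabels) != nrow(d))
      return("one channel label per row is required")
    if (length(object@samplingRate) != 1 || object@samplingRate <= 0)
      return("samplingRate must be a single positive number")
    TRUE
  })

#' Binary EEG code (biometric template)
#'
#' Fixed-length bit vector obtained by flattening the binarized covariance
#' matrix row-major; length is always the square of the channel count
#' (400 bits for 20 channels).
#'
#' @slot bits integer vector of 0/1.
#' @slot sourceChannels number of channels the code was derived from.
#' @exportClass EEGCode
setClass("EEGCode",
  representation(bits = "integer", sourceChannels = "integer"),
  validity = function(object) {
    if (!all(object@bits %in% c(0L, 1L))) return("bits must be 0/1")
    if (length(object@bits) != object@sourceChannels^2)
      return("code length must equal sourceChannels^2")
    TRUE
  })

#' Galois field GF(2^m)
#'
#' Log/antilog tables over the 2^m - 1 nonzero elements, built from a
#' primitive polynomial. Elements are represented by the integer whose bits
#' are the polynomial coefficients.
#'
#' @slot m field exponent.
#' @slot primitivePoly primitive polynomial as an integer bit mask (LSB = x^0).
#' @slot logTable integer vector; logTable[value] = exponent of alpha.
#' @slot antilogTable integer vector; antilogTable[e + 1] = value of alpha^e.
#' @exportClass GaloisField
setClass("GaloisField",
  representation(m = "integer", primitivePoly = "integer",
                 logTable = "integer", antilogTable = "integer"),
  validity = function(object) {
    n <- 2L^object@m - 1L
    if (length(object@antilogTable) != n)
      return("antilog table must have 2^m - 1 entries")
    if (anyDuplicated(object@antilogTable))
      return("polynomial is not primitive: powers of alpha repeat")
    if (!identical(sort(object@antilogTable), seq_len(n)))
      return("powers of alpha do not enumerate the nonzero elements")
    TRUE
  })

#' Binary BCH code specification
#'
#' Code of length n = 2^m - 1 with designed error-correction capability t and
#' generator polynomial equal to the least common multiple of the minimal
#' polynomials of alpha^1 ... alpha^2t. Message length k = n - deg(generator).
#'
#' @slot field the underlying \linkS4class{GaloisField}.
#' @slot n code length.
#' @slot k message length.
#' @slot t designed error-correction capability.
#' @slot generator generator polynomial as a 0/1 coefficient vector (LSB first).
#' @exportClass BCHCode
setClass("BCHCode",
  representation(field = "GaloisField", n = "integer", k = "integer",
                 t = "integer", generator = "integer"),
  validity = function(object) {
    if (object@n != 2L^object@field@m - 1L) return("n must equal 2^m - 1")
    if (object@k < 1L) return("message length k must be at least 1")
    deg <- length(object@generator) - 1L
    if (object@k != object@n - deg) return("k must equal n - deg(generator)")
    if (object@generator[length(object@generator)] != 1L)
      return("generator polynomial must be monic")
    TRUE
  })

#' Public commitment key (p, q, g, h)
#'
#' Parameters of the discrete-log commitment: primes p, q with q | p - 1, and
#' two generators g, h of the order-q subgroup of Z_p^*. The exponent a with
#' h = g^a is discarded at setup; binding rests on its discrete logarithm
#' being unknown. Big integers are stored as lowercase hex strings.
#'
#' @slot p,q,g,h hex strings.
#' @slot bitsP,bitsQ nominal bit sizes used at generation.
#' @exportClass CommitKey
setClass("CommitKey",
  representation(p = "character", q = "character", g = "character",
                 h = "character", bitsP = "integer", bitsQ = "integer"),
  validity = function(object) {
    one <- "1"
    if (.bnCmp(object@g, one) == 0) return("g must not be 1")
    if (.bnCmp(object@h, one) == 0) return("h must not be 1")
    if (.bnCmp(.bnMod(.bnSub(object@p, one), object@q), "0") != 0)
      return("q must divide p - 1")
    if (.bnCmp(.bnModExp(object@g, object@q, object@p), one) != 0)
      return("g is not in the order-q subgroup")
    if (.bnCmp(.bnModExp(object@h, object@q, object@p), one) != 0)
      return("h is not in the order-q subgroup")
    TRUE
  })

#' Commitment (phi, delta)
#'
#' phi = g^c h^x (mod p) binds codeword c and witness x; delta = x XOR c is
#' the public difference vector (the sketch). Neither reveals c or x alone.
#'
#' @slot phi hex string, element of the order-q subgroup.
#' @slot delta integer 0/1 vector of length n.
#' @exportClass Commitment
setClass("Commitment",
  representation(phi = "character", delta = "integer"),
  validity = function(object) {
    if (!all(object@delta %in% c(0L, 1L))) return("delta must be 0/1")
    TRUE
  })

#' Stored enrolment template (helper data)
#'
#' The only record persisted after enrolment: the commitment value phi, the
#' difference vector delta, and references to the codec / key parameters.
#' It contains neither the EEG code, the codeword, nor the key.
#'
#' @slot phi hex string.
#' @slot delta integer 0/1 vector.
#' @slot codecId identifier of the BCH parameters (e.g. "bch-m9-t87").
#' @slot keyId identifier (digest) of the commitment key parameters.
#' @slot subjectLabel optional subject label.
#' @exportClass EEGTemplate
setClass("EEGTemplate",
  representation(phi = "character", delta = "integer", codecId = "character",
                 keyId = "character", subjectLabel = "character"))

#' Authentication result
#'
#' @slot accepted logical.
#' @slot releasedKey integer 0/1 vector of length k when accepted, length 0
#'   otherwise.
#' @slot keyDigest convenience hex digest of the released key ("" on reject).
#' @exportClass AuthResult
setClass("AuthResult",
  representation(accepted = "logical", releasedKey = "integer",
                 keyDigest = "character"),
  validity = function(object) {
    if (!object@accepted && length(object@releasedKey) > 0)
      return("releasedKey must be absent when rejected")
    TRUE
  })

#' Synthetic subject model
#'
#' A subject is a stable spatial covariance structure; recordings are drawn
#' from a zero-mean multivariate normal around a session-perturbed version of
#' this base covariance.
#'
#' @slot subjectId identifier.
#' @slot baseCovariance symmetric positive-definite channels x channels matrix.
#' @slot seed integer seed the model was built from.
#' @exportClass SubjectModel
setClass("SubjectModel",
  representation(subjectId = "character", baseCovariance = "matrix",
                 seed = "integer"),
  validity = function(object) {
    B <- object@baseCovariance
    if (nrow(B) != ncol(B)) return("baseCovariance must be square")
    if (max(abs(B - t(B))) > 1e-8) return("baseCovariance must be symmetric")
    ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) return("baseCovariance must be positive-definite")
    TRUE
  })

#' Synthetic EEG cohort
#'
#' A list of recordings with parallel subject ids and the generating
#' configuration, emulating a multi-subject study (by default 20 channels,
#' 1000 samples per recording at 256 Hz).
#'
#' @slot recordings list of \linkS4class{EEGRecording}.
#' @slot subjectIds character vector parallel to recordings.
#' @slot config the generating configuration (list).
#' @exportClass EEGCohort
setClass("EEGCohort",
  representation(recordings = "list", subjectIds = "character",
                 config = "list"),
  validity = function(object) {
    if (length(object@recordings) != length(object@subjectIds))
      return("one subject id per recording is required")
    TRUE
  })

#' Genuine and impostor score set
#'
#' Normalized Hamming distances for all same-subject (genuine) and
#' cross-subject (impostor) pairs, with the raw differing-bit counts kept for
#' histogram-based analyses.
#'
#' @slot genuine,impostor normalized distances in [0, 1].
#' @slot genuineBits,impostorBits raw differing-bit counts.
#' @slot codeLength bit length of the compared codes.
#' @exportClass ScoreSet
setClass("ScoreSet",
  representation(genuine = "numeric", impostor = "numeric",
                 genuineBits = "integer", impostorBits = "integer",
                 codeLength = "integer"),
  validity = function(object) {
    if (any(object@genuine < 0 | object@genuine > 1) ||
        any(object@impostor < 0 | object@impostor > 1))
      return("normalized distances must lie in [0, 1]")
    TRUE
  })
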