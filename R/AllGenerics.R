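# Accessor generics and show methods.

#' @rdname EEGRecording-class
#' @param object an object.
#' @export
setGeneric("eegData", function(object) standardGeneric("eegData"))

#' @rdname EEGRecording-class
#' @export
setGeneric("channelLabels", function(object) standardGeneric("channelLabels"))

#' @rdname EEGRecording-class
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname EEGCode-class
#' @param object an object.
#' @export
setGeneric("codeBits", function(object) standardGeneric("codeBits"))

#' @rdname EEGCohort-class
#' @param object an object.
#' @export
setGeneric("recordings", function(object) standardGeneric("recordings"))

#' @rdname EEGCohort-class
#' @export
setGeneric("subjectIds", function(object) standardGeneric("subjectIds"))

#' @rdname ScoreSet-class
#' @param object an object.
#' @export
setGeneric("genuineScores", function(object) standardGeneric("genuineScores"))

#' @rdname ScoreSet-class
#' @export
setGeneric("impostorScores", function(object) standardGeneric("impostorScores"))

#' @rdname AuthResult-class
#' @param object an object.
#' @export
setGeneric("isAccepted", function(object) standardGeneric("isAccepted"))

#' @rdname AuthResult-class
#' @export
setGeneric("releasedKey", function(object) standardGeneric("releasedKey"))

#' @rdname EEGRecording-class
#' @exportMethod eegData
setMethod("eegData", "EEGRecording", function(object) object@data)

#' @rdname EEGRecording-class
#' @exportMethod channelLabels
setMethod("channelLabels", "EEGRecording", function(object) object@channelLabels)

#' @rdname EEGRecording-class
#' @exportMethod samplingRate
setMethod("samplingRate", "EEGRecording", function(object) object@samplingRate)

#' @rdname EEGCode-class
#' @exportMethod codeBits
setMethod("codeBits", "EEGCode", function(object) object@bits)

#' @rdname EEGCohort-class
#' @exportMethod recordings
setMethod("recordings", "EEGCohort", function(object) object@recordings)

#' @rdname EEGCohort-class
#' @exportMethod subjectIds
setMethod("subjectIds", "EEGCohort", function(object) object@subjectIds)

#' @rdname ScoreSet-class
#' @exportMethod genuineScores
setMethod("genuineScores", "ScoreSet", function(object) object@genuine)

#' @rdname ScoreSet-class
#' @exportMethod impostorScores
setMethod("impostorScores", "ScoreSet", function(object) object@impostor)

#' @rdname AuthResult-class
#' @exportMethod isAccepted
setMethod("isAccepted", "AuthResult", function(object) object@accepted)

#' @rdname AuthResult-class
#' @exportMethod releasedKey
setMethod("releasedKey", "AuthResult", function(object) object@releasedKey)

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples @ %g Hz\n",
              nrow(object@data), ncol(object@data), object@samplingRate))
  cat("  channels:", paste(head(object@channelLabels, 8), collapse = " "),
      if (length(object@channelLabels) > 8) "..." else "", "\n")
})

setMethod("show", "EEGCode", function(object) {
  cat(sprintf("EEGCode: %d bits (%d channels), weight %d\n",
              length(object@bits), object@sourceChannels, sum(object@bits)))
})

setMethod("show", "GaloisField", function(object) {
  cat(sprintf("GaloisField GF(2^%d): %d nonzero elements, primitive poly 0x%x\n",
              object@m, 2L^object@m - 1L, object@primitivePoly))
})

setMethod("show", "BCHCode", function(object) {
  cat(sprintf("BCHCode(n = %d, k = %d, t = %d) over GF(2^%d), deg(g) = %d\n",
              object@n, object@k, object@t, object@field@m,
              length(object@generator) - 1L))
})

setMethod("show", "CommitKey", function(object) {
  cat(sprintf("CommitKey: |p| = %d bits, |q| = %d bits (order-q subgroup of Z_p*)\n",
              .bnBitLength(object@p), .bnBitLength(object@q)))
})

setMethod("show", "Commitment", function(object) {
  cat(sprintf("Commitment: phi = %s... , |delta| = %d bits\n",
              substr(object@phi, 1, 16), length(object@delta)))
})

setMethod("show", "EEGTemplate", function(object) {
  cat(sprintf("EEGTemplate[%s]: codec %s, key %s, |delta| = %d bits\n",
              if (length(object@subjectLabel)) object@subjectLabel else "?",
              object@codecId, object@keyId, length(object@delta)))
})

setMethod("show", "AuthResult", function(object) {
  if (object@accepted)
    cat(sprintf("AuthResult: ACCEPT, released %d-bit key (digest %s)\n",
                length(object@releasedKey), object@keyDigest))
  else cat("AuthResult: REJECT\n")
})

setMethod("show", "SubjectModel", function(object) {
  cat(sprintf("SubjectModel %s: %d channels, seed %d\n", object@subjectId,
              nrow(object@baseCovariance), object@seed))
})

setMethod("show", "EEGCohort", function(object) {
  cat(sprintf("EEGCohort: %d recordings, %d subjects\n",
              length(object@recordings), length(unique(object@subjectIds))))
})

setMethod("show", "ScoreSet", function(object) {
  cat(sprintf("ScoreSet: %d genuine, %d impostor scores (code length %d)\n",
              length(object@genuine), length(object@impostor),
              object@codeLength))
})

#' @rdname EEGCohort-class
#' @param x an \linkS4class{EEGCohort}.
#' @exportMethod length
setMethod("length", "EEGCohort", function(x) length(x@recordings))
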