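# The biometric cryptosystem: enrolment binds a fresh random key to the
# reference EEG code; authentication re-presents a noisy code, corrects up
# to t bit errors, and releases the key iff the recomputed commitment
# matches. Only helper data (phi, delta) is persisted.

#' Enrol a biometric code and bind a fresh key
#'
#' Draws a uniform k-bit key kappa under the seed, encodes it to a codeword
#' c, zero-pads the biometric code to the code length n as witness x_ref, and
#' stores only phi = g^c h^x_ref (mod p) and delta = x_ref XOR c. Neither
#' kappa, c nor x_ref appears in the template.
#'
#' @param code an \linkS4class{EEGCode} or a raw 0/1 bit vector.
#' @param key a \linkS4class{CommitKey}.
#' @param codec a \linkS4class{BCHCode}.
#' @param seed integer seed for the key draw.
#' @param subjectLabel optional label stored in the template.
#' @return list with elements \code{template} (\linkS4class{EEGTemplate}) and
#'   \code{kappa} (integer 0/1 vector of length k).
#' @export
enrolCode <- function(code, key, codec, seed = 1, subjectLabel = "") {
  bits <- if (is(code, "EEGCode")) codeBits(code) else as.integer(code)
  if (length(bits) > codec@n)
    stop("biometric code longer than the code length n")
  xref <- padCode(bits, codec@n)
  kappa <- .withSeed(seed, randomBits(codec@k))
  cw <- bchEncode(codec, kappa)
  com <- commitCode(key, cw, xref)
  tmpl <- new("EEGTemplate", phi = com@phi, delta = com@delta,
              codecId = bchId(codec), keyId = keyDigest(key),
              subjectLabel = as.character(subjectLabel))
  list(template = tmpl, kappa = kappa)
}

#' Enrol from one or more recordings
#'
#' Encodes the recording(s) and calls \code{\link{enrolCode}}. With several
#' recordings and \code{majorityVote = TRUE}, the reference code is the
#' per-bit majority over the encoded samples (ties to 1); by default a single
#' recording is used.
#'
#' @param rec an \linkS4class{EEGRecording} or a list of them.
#' @param key a \linkS4class{CommitKey}.
#' @param codec a \linkS4class{BCHCode}.
#' @param seed integer seed for the key draw.
#' @param subjectLabel optional label.
#' @param majorityVote combine multiple recordings by per-bit majority.
#' @return as \code{\link{enrolCode}}.
#' @export
enrol <- function(rec, key, codec, seed = 1, subjectLabel = "",
                  majorityVote = FALSE) {
  if (is(rec, "EEGRecording")) rec <- list(rec)
  if (length(rec) > 1 && !majorityVote)
    stop("multiple recordings given; set majorityVote = TRUE to combine them")
  codes <- lapply(rec, function(r) codeBits(encodeEEG(r)))
  bits <- if (length(codes) == 1) codes[[1]]
          else as.integer(colMeans(do.call(rbind, codes)) >= 0.5)
  enrolCode(bits, key, codec, seed = seed, subjectLabel = subjectLabel)
}

#' Authenticate a probe code against a template
#'
#' Computes c-hat = x_test XOR delta, decodes it, recomputes
#' x' = delta XOR c' and phi' = g^c' h^x' (mod p), and accepts iff phi'
#' equals the stored phi; on acceptance the enrolled key is re-extracted and
#' released. Rejection is a result, not an error.
#'
#' @param code probe \linkS4class{EEGCode} or raw 0/1 bit vector.
#' @param template an \linkS4class{EEGTemplate}.
#' @param key the \linkS4class{CommitKey} used at enrolment.
#' @param codec the \linkS4class{BCHCode} used at enrolment.
#' @return an \linkS4class{AuthResult}.
#' @export
authenticateCode <- function(code, template, key, codec) {
  bits <- if (is(code, "EEGCode")) codeBits(code) else as.integer(code)
  if (bchId(codec) != template@codecId)
    stop("codec does not match the template (", template@codecId, ")")
  if (keyDigest(key) != template@keyId)
    stop("commitment key does not match the template")
  xtest <- padCode(bits, codec@n)
  com <- new("Commitment", phi = template@phi, delta = template@delta)
  msg <- openCommitment(key, com, xtest, codec)
  if (is.null(msg))
    new("AuthResult", accepted = FALSE, releasedKey = integer(0),
        keyDigest = "")
  else
    new("AuthResult", accepted = TRUE, releasedKey = msg,
        keyDigest = bitDigest(msg))
}

#' @rdname authenticateCode
#' @param rec probe \linkS4class{EEGRecording}.
#' @export
authenticate <- function(rec, template, key, codec) {
  authenticateCode(encodeEEG(rec), template, key, codec)
}

#' Serialize / deserialize a template as JSON
#'
#' The template is the only persisted record: phi (hex), delta (hex-packed
#' bits plus its bit length), codec and key identifiers, and the optional
#' subject label.
#'
#' @param template an \linkS4class{EEGTemplate}.
#' @param path file path.
#' @return \code{readTemplate} returns an \linkS4class{EEGTemplate}.
#' @export
writeTemplate <- function(template, path) {
  obj <- list(phi = template@phi, delta = bitsToHex(template@delta),
              delta_bits = length(template@delta), codec = template@codecId,
              key = template@keyId, subject = template@subjectLabel)
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeTemplate
#' @export
readTemplate <- function(path) {
  o <- jsonlite::read_json(path)
  new("EEGTemplate", phi = o$phi, delta = hexToBits(o$delta, o$delta_bits),
      codecId = o$codec, keyId = o$key, subjectLabel = o$subject)
}
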