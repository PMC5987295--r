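# Binary BCH codes: generator construction via the lcm of minimal
# polynomials, systematic encoding, bounded-distance decoding (syndromes,
# Berlekamp-Massey, Chien search; hot path in C++), and the zero-padding that
# reconciles the 400-bit EEG code with the natural code length 2^m - 1.

#' Construct a BCH code specification
#'
#' Builds the generator polynomial as lcm(m_1(x), ..., m_2t(x)), the least
#' common multiple of the minimal polynomials of alpha^1 ... alpha^2t
#' (designed distance 2t + 1), and derives the message length
#' k = n - deg(generator).
#'
#' @param m field exponent; code length is n = 2^m - 1.
#' @param t designed error-correction capability, t >= 1.
#' @param primitivePoly optional primitive polynomial override for the field.
#' @return a \linkS4class{BCHCode}.
#' @examples
#' spec <- bchCode(4, 1) # the (15, 11) Hamming-equivalent BCH code
#' c(spec@n, spec@k, spec@t)
#' @export
bchCode <- function(m, t, primitivePoly = NULL) {
  if (t < 1) stop("t must be at least 1")
  field <- buildField(m, primitivePoly)
  n <- fieldOrder(field)
  if (2 * t + 1 > n)
    stop("capability-too-large: designed distance 2t + 1 exceeds n = ", n)
  seen <- logical(n)
  gen <- 1L
  for (pw in seq_len(2L * as.integer(t))) {
    rep0 <- min(conjugacyClass(field, pw))
    if (seen[rep0]) next
    seen[rep0] <- TRUE
    gen <- polyMulGF2(gen, minimalPolynomial(field, pw))
  }
  k <- n - (length(gen) - 1L)
  if (k < 1L)
    stop("capability-too-large: t = ", t, " leaves no message bits at n = ", n)
  new("BCHCode", field = field, n = as.integer(n), k = as.integer(k), t = as.integer(t),
      generator = gen)
}

#' Systematic BCH encoding
#'
#' Maps a k-bit message to the n-bit codeword x^(n-k) M(x) + rem, where rem
#' is the remainder of x^(n-k) M(x) modulo the generator polynomial. The
#' message occupies the high-degree positions (tail of the bit vector);
#' parity fills the head.
#'
#' @param spec a \linkS4class{BCHCode}.
#' @param message integer 0/1 vector of length k (coefficient of x^0 first).
#' @return integer 0/1 codeword of length n.
#' @export
bchEncode <- function(spec, message) {
  message <- as.integer(message)
  if (length(message) != spec@k)
    stop("message must have exactly k = ", spec@k, " bits")
  if (!all(message %in% c(0L, 1L))) stop("message bits must be 0/1")
  shifted <- c(rep(0L, spec@n - spec@k), message)
  rem <- polyModGF2(shifted, spec@generator)
  cw <- shifted
  cw[seq_along(rem)] <- bitwXor(cw[seq_along(rem)], rem)
  cw
}

#' Bounded-distance BCH decoding
#'
#' Computes the 2t syndromes, runs Berlekamp-Massey for the error locator and
#' Chien search for its roots, and corrects up to t bit errors. If no
#' codeword lies within Hamming distance t (locator degree above t, root
#' count mismatch, or residual syndromes), the received word is declared
#' invalid and \code{NULL} is returned -- invalidity is a value, not an error.
#'
#' @param spec a \linkS4class{BCHCode}.
#' @param received integer 0/1 vector of length n.
#' @return corrected codeword (integer 0/1 vector) or \code{NULL}.
#' @export
bchDecode <- function(spec, received) {
  received <- as.integer(received)
  if (length(received) != spec@n)
    stop("received word must have exactly n = ", spec@n, " bits")
  out <- .bchDecodeCpp(received, spec@field@logTable, spec@field@antilogTable,
                       spec@t)
  if (length(out) == 0L) NULL else out
}

#' Syndromes of a word
#'
#' S_j = r(alpha^j) for j = 1 ... 2t; all zero iff the word is a codeword.
#'
#' @param spec a \linkS4class{BCHCode}.
#' @param word integer 0/1 vector of length n.
#' @return integer vector of 2t field-element values.
#' @export
bchSyndromes <- function(spec, word) {
  word <- as.integer(word)
  if (length(word) != spec@n) stop("word must have n bits")
  .bchSyndromesCpp(word, spec@field@logTable, spec@field@antilogTable, spec@t)
}

#' Extract the message from a systematic codeword
#'
#' Inverse of \code{bchEncode}: reads the k message bits from the systematic
#' positions after checking that the input is a valid codeword.
#'
#' @param spec a \linkS4class{BCHCode}.
#' @param codeword integer 0/1 vector of length n with all syndromes zero.
#' @return integer 0/1 vector of length k.
#' @export
extractMessage <- function(spec, codeword) {
  codeword <- as.integer(codeword)
  if (length(codeword) != spec@n) stop("codeword must have n bits")
  if (any(bchSyndromes(spec, codeword) != 0L))
    stop("input is not a valid codeword")
  codeword[(spec@n - spec@k + 1L):spec@n]
}

#' Zero-pad a biometric code to the code length n
#'
#' The 400-bit EEG code is shorter than the natural BCH length n = 2^m - 1
#' (511 for m = 9); the tail positions are fixed to zero on both enrolment
#' and probe codes, so they never carry errors and the full correction
#' capability is spent on the biometric positions. \code{unpadCode} inverts
#' the padding.
#'
#' @param bits integer 0/1 vector (the biometric code).
#' @param n target length.
#' @return integer 0/1 vector of length n.
#' @export
padCode <- function(bits, n) {
  bits <- as.integer(bits)
  if (length(bits) > n) stop("code longer than target length n")
  c(bits, rep(0L, n - length(bits)))
}

#' @rdname padCode
#' @param word padded integer 0/1 vector of length n.
#' @param len original code length.
#' @return integer 0/1 vector of length len.
#' @export
unpadCode <- function(word, len) {
  word <- as.integer(word)
  if (length(word) < len) stop("padded word shorter than code length")
  word[seq_len(len)]
}

#' Identifier string for a BCH parameter set
#' @param spec a \linkS4class{BCHCode}.
#' @return string like "bch-m9-t87".
#' @export
bchId <- function(spec) sprintf("bch-m%d-t%d", spec@field@m, spec@t)

#' Serialize / deserialize BCH parameters as JSON
#'
#' Writes m, t, n, k and the primitive and generator polynomials as hex
#' bit-strings; reading rebuilds the code from (m, t, primitive polynomial)
#' and checks the stored generator matches.
#'
#' @param spec a \linkS4class{BCHCode}.
#' @param path file path.
#' @return \code{readBCHCode} returns a \linkS4class{BCHCode}.
#' @export
writeBCHCode <- function(spec, path) {
  obj <- list(
    m = spec@field@m, t = spec@t, n = spec@n, k = spec@k,
    primitive_poly = bitsToHex(rev(intToBits(spec@field@primitivePoly)[1:32] == 1) * 1L),
    generator = bitsToHex(rev(spec@generator))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeBCHCode
#' @export
readBCHCode <- function(path) {
  obj <- jsonlite::read_json(path)
  prim <- sum(hexToBits(obj$primitive_poly, 32) * 2^(31:0))
  spec <- bchCode(obj$m, obj$t, primitivePoly = prim)
  stored <- hexToBits(obj$generator, spec@n - spec@k + 1L)
  if (!identical(rev(stored), spec@generator))
    stop("stored generator polynomial does not match (m, t, primitive)")
  spec
}

# Default operational code: n = 511 with designed capability t = 87, the
# empirically tolerated error count for 400-bit EEG codes. Built lazily and
# cached (the generator construction is deterministic).
.cache <- new.env(parent = emptyenv())

#' Default BCH code (m = 9, t = 87)
#'
#' The operational code for 400-bit EEG templates: length n = 511, designed
#' correction capability t = 87; the message length k follows from the
#' generator degree. Cached after first construction.
#'
#' @return a \linkS4class{BCHCode}.
#' @export
defaultBCHCode <- function() {
  if (is.null(.cache$defaultBCH)) .cache$defaultBCH <- bchCode(9, 87)
  .cache$defaultBCH
}
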