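# Bit-vector helpers. Bit vectors are integer vectors of 0/1; the integer
# embedding used for commitment exponents is big-endian (first bit = most
# significant), so an n-bit string maps injectively into [0, 2^n).

.HEX_DIGITS <- strsplit("0123456789abcdef", "")[[1]]

#' Convert a 0/1 bit vector to a hex string (big-endian)
#'
#' The bit vector is left-padded with zeros to a multiple of 4 bits; leading
#' zero digits are kept so that \code{hexToBits} can invert exactly given the
#' original length.
#'
#' @param bits integer vector of 0/1.
#' @return lowercase hex string.
#' @export
bitsToHex <- function(bits) {
  stopifnot(all(bits %in% c(0L, 1L)))
  pad <- (4L - length(bits) %% 4L) %% 4L
  b <- c(rep(0L, pad), as.integer(bits))
  nib <- matrix(b, nrow = 4L)
  vals <- as.integer(8L * nib[1L, ] + 4L * nib[2L, ] + 2L * nib[3L, ] + nib[4L, ])
  paste(.HEX_DIGITS[vals + 1L], collapse = "")
}

#' Convert a hex string to a 0/1 bit vector of a given length
#'
#' @param hex lowercase or uppercase hex string.
#' @param nbits target length; the value must fit in nbits bits.
#' @return integer vector of 0/1, big-endian.
#' @export
hexToBits <- function(hex, nbits) {
  digs <- match(strsplit(tolower(hex), "")[[1]], .HEX_DIGITS) - 1L
  if (anyNA(digs)) stop("invalid hex string")
  bits <- as.integer(vapply(digs, function(v) {
    c(v %/% 8L, (v %/% 4L) %% 2L, (v %/% 2L) %% 2L, v %% 2L)
  }, integer(4)))
  if (length(bits) > nbits) {
    extra <- bits[seq_len(length(bits) - nbits)]
    if (any(extra != 0L)) stop("value does not fit in ", nbits, " bits")
    bits <- bits[-seq_len(length(bits) - nbits)]
  } else if (length(bits) < nbits) {
    bits <- c(rep(0L, nbits - length(bits)), bits)
  }
  bits
}

#' Bitwise XOR of two equal-length bit vectors
#' @param a,b integer vectors of 0/1.
#' @return integer vector of 0/1.
#' @export
xorBits <- function(a, b) {
  if (length(a) != length(b)) stop("bit vectors differ in length")
  bitwXor(as.integer(a), as.integer(b))
}

#' Seeded uniform random bits
#' @param n number of bits.
#' @return integer vector of 0/1 drawn from the current R RNG stream.
#' @export
randomBits <- function(n) {
  sample(c(0L, 1L), n, replace = TRUE)
}

# 32-bit FNV-1a over the bit characters; convenience key digest, not a
# cryptographic hash.
.fnv1a32 <- function(bytes) {
  h <- 2166136261 # 0x811c9dc5; kept as a double, exact below 2^53
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # h * 16777619 mod 2^32 without integer overflow: 16-bit split
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Short hex digest of a bit vector (FNV-1a based)
#'
#' A convenience fingerprint for logging released keys and referencing
#' parameter sets; not a cryptographic hash.
#'
#' @param bits integer vector of 0/1 (or a character string).
#' @return 8-hex-digit string.
#' @export
bitDigest <- function(bits) {
  if (is.character(bits)) bytes <- utf8ToInt(paste(bits, collapse = ""))
  else bytes <- as.integer(bits) + 48L
  .fnv1a32(bytes)
}
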