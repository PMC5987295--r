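# Galois field GF(2^m) construction and binary polynomial arithmetic.
# Field elements are integers whose bits are polynomial coefficients; the
# multiplicative group is tabulated as powers of the primitive element alpha.

# Default primitive polynomials per m (bit mask, LSB = x^0). Standard
# low-weight choices, e.g. x^4 + x + 1 for m = 4 and x^9 + x^4 + 1 for m = 9.
.PRIMITIVE_POLYS <- c(
  `2` = 7L, `3` = 11L, `4` = 19L, `5` = 37L, `6` = 67L, `7` = 137L,
  `8` = 285L, `9` = 529L, `10` = 1033L, `11` = 2053L, `12` = 4179L,
  `13` = 8219L, `14` = 17475L, `15` = 32771L, `16` = 69643L
)

#' Build GF(2^m) log/antilog tables
#'
#' Tabulates the powers of the primitive element alpha (a root of the
#' primitive polynomial) over the 2^m - 1 nonzero field elements. Validity
#' checks that the powers enumerate every nonzero element exactly once, i.e.
#' that the polynomial really is primitive.
#'
#' @param m field exponent, 2 to 16.
#' @param primitivePoly optional primitive polynomial as an integer bit mask
#'   (LSB = constant term); defaults to a published low-weight choice.
#' @return a \linkS4class{GaloisField}.
#' @examples
#' gf <- buildField(4)
#' fieldOrder(gf) # 15 nonzero elements
#' @export
buildField <- function(m, primitivePoly = NULL) {
  if (m < 2 || m > 16) stop("m must be between 2 and 16")
  m <- as.integer(m)
  if (is.null(primitivePoly)) primitivePoly <- .PRIMITIVE_POLYS[[as.character(m)]]
  primitivePoly <- as.integer(primitivePoly)
  n <- 2L^m - 1L
  antilog <- integer(n)
  val <- 1L
  overflow <- 2L^m
  reduce <- primitivePoly - overflow # low bits of the polynomial
  for (e in seq_len(n)) {
    antilog[e] <- val
    val <- val * 2L
    if (val >= overflow) val <- bitwXor(val - overflow, reduce)
  }
  logTable <- integer(n)
  logTable[antilog] <- seq_len(n) - 1L
  new("GaloisField", m = m, primitivePoly = primitivePoly,
      logTable = logTable, antilogTable = antilog)
}

#' Number of nonzero elements of a field
#' @param field a \linkS4class{GaloisField}.
#' @return 2^m - 1.
#' @export
fieldOrder <- function(field) 2L^field@m - 1L

#' Multiply field elements
#'
#' Vectorized multiplication in GF(2^m) via the log/antilog tables.
#'
#' @param field a \linkS4class{GaloisField}.
#' @param a,b integer element values (0 allowed).
#' @return element values of a * b.
#' @export
gfMul <- function(field, a, b) {
  n <- fieldOrder(field)
  r <- integer(max(length(a), length(b)))
  a <- rep_len(as.integer(a), length(r)); b <- rep_len(as.integer(b), length(r))
  nz <- a != 0L & b != 0L
  e <- (field@logTable[a[nz]] + field@logTable[b[nz]]) %% n
  r[nz] <- field@antilogTable[e + 1L]
  r
}

#' Power of the primitive element
#' @param field a \linkS4class{GaloisField}.
#' @param e integer exponent(s), reduced mod 2^m - 1.
#' @return element value(s) of alpha^e.
#' @export
gfAlphaPow <- function(field, e) {
  n <- fieldOrder(field)
  field@antilogTable[(as.integer(e) %% n) + 1L]
}

#' Evaluate a binary polynomial at a field element
#' @param field a \linkS4class{GaloisField}.
#' @param poly 0/1 coefficient vector, constant term first.
#' @param x element value.
#' @return element value of poly(x) (Horner scheme).
#' @export
gfPolyEval <- function(field, poly, x) {
  acc <- 0L
  for (k in rev(seq_along(poly))) {
    acc <- bitwXor(gfMul(field, acc, x), as.integer(poly[k]))
  }
  acc
}

# ---- binary (GF(2)) polynomial arithmetic on 0/1 coefficient vectors ------

.polyTrim <- function(p) {
  last <- max(c(1L, which(p != 0L)))
  p[seq_len(last)]
}

#' Multiply binary polynomials
#' @param a,b 0/1 coefficient vectors (constant term first).
#' @return 0/1 coefficient vector of the product over GF(2).
#' @export
polyMulGF2 <- function(a, b) {
  a <- .polyTrim(as.integer(a)); b <- .polyTrim(as.integer(b))
  r <- integer(length(a) + length(b) - 1L)
  for (i in which(a == 1L)) {
    idx <- (i - 1L) + seq_along(b)
    r[idx] <- bitwXor(r[idx], b)
  }
  .polyTrim(r)
}

#' Remainder of binary polynomial division
#' @param a dividend, 0/1 coefficient vector.
#' @param m divisor, 0/1 coefficient vector (nonzero).
#' @return 0/1 coefficient vector of a mod m over GF(2).
#' @export
polyModGF2 <- function(a, m) {
  a <- .polyTrim(as.integer(a)); m <- .polyTrim(as.integer(m))
  if (length(m) == 1L && m[1L] == 0L) stop("division by zero polynomial")
  degm <- length(m) - 1L
  while (length(a) - 1L >= degm && any(a != 0L)) {
    a <- .polyTrim(a)
    if (length(a) - 1L < degm) break
    shift <- length(a) - length(m)
    idx <- shift + seq_along(m)
    a[idx] <- bitwXor(a[idx], m)
    a <- a[-length(a)]
    if (length(a) == 0L) a <- 0L
  }
  .polyTrim(a)
}

#' Minimal polynomial of alpha^power over GF(2)
#'
#' Lowest-degree binary polynomial having alpha^power as a root, built as the
#' product over the conjugacy class \{power * 2^j mod (2^m - 1)\}.
#'
#' @param field a \linkS4class{GaloisField}.
#' @param power integer, 1 <= power <= 2^m - 2.
#' @return 0/1 coefficient vector (constant term first).
#' @export
minimalPolynomial <- function(field, power) {
  n <- fieldOrder(field)
  if (power < 1 || power > n - 1) stop("power out of range")
  cls <- conjugacyClass(field, power)
  # product of (x + alpha^s) with coefficients in the field
  coef <- 1L # constant polynomial 1 (field-element coefficients)
  for (s in cls) {
    root <- gfAlphaPow(field, s)
    shifted <- c(0L, coef)                       # x * coef
    scaled <- c(gfMul(field, coef, root), 0L)    # root * coef
    coef <- bitwXor(shifted, scaled)
  }
  if (!all(coef %in% c(0L, 1L)))
    stop("internal error: minimal polynomial not binary")
  as.integer(coef)
}

#' Conjugacy class (cyclotomic coset) of an exponent
#' @param field a \linkS4class{GaloisField}.
#' @param power integer exponent.
#' @return sorted integer vector \{power * 2^j mod (2^m - 1)\}.
#' @export
conjugacyClass <- function(field, power) {
  n <- fieldOrder(field)
  cls <- integer(0)
  s <- power %% n
  repeat {
    cls <- c(cls, s)
    s <- (s * 2L) %% n
    if (s == cls[1L]) break
  }
  sort(cls)
}
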