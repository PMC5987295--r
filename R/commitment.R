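# Discrete-log commitment over a prime-order subgroup of Z_p^*:
# Setup (prime/parameter generation), Commit (phi = g^c h^x mod p with the
# XOR difference vector delta = x XOR c), Open (decode-and-recompute), and
# the empirical hiding/binding game harnesses.
#
# Bit strings embed as exponents big-endian; q is chosen with at least n + 1
# bits so every n-bit string is below q. Arithmetic is NOT constant-time:
# this is a research artifact, not a hardened implementation.

.MR_ROUNDS <- 32L

.randomOddHex <- function(bits) {
  b <- randomBits(bits)
  b[1] <- 1L            # full bit length
  b[bits] <- 1L         # odd
  bitsToHex(b)
}

.randomHexBelow <- function(qhex, bits) {
  # rejection-free: random 'bits'-bit value reduced mod q
  .bnMod(bitsToHex(randomBits(bits + 64L)), qhex)
}

#' Generate commitment parameters (Setup)
#'
#' Generates primes q (bitsQ bits) and p = q r + 1 (about bitsP bits), a
#' generator g of the order-q subgroup of Z_p^* (g = z^r mod p for random z,
#' retried until g != 1), and h = g^a for a random secret a in [1, q - 1].
#' The exponent a is discarded unless \code{retainTrapdoor = TRUE}, in which
#' case it is attached as the attribute \code{"trapdoor"} -- useful only for
#' demonstrating in the binding-game harness that binding rests on discarding
#' it.
#'
#' @param bitsP target bit size of p (must exceed bitsQ).
#' @param bitsQ bit size of q; must be at least n + 1 for an n-bit code so
#'   that bit strings embed injectively as exponents below q.
#' @param seed integer seed (the whole key is a function of it).
#' @param retainTrapdoor keep a = log_g h as an attribute (insecure; for the
#'   binding-game demonstration only).
#' @param maxIter candidate budget for each prime search.
#' @return a \linkS4class{CommitKey}.
#' @examples
#' key <- commitSetup(bitsP = 80, bitsQ = 40, seed = 1)
#' @export
commitSetup <- function(bitsP = 576, bitsQ = 520, seed = 1,
                        retainTrapdoor = FALSE, maxIter = 100000L) {
  if (bitsP <= bitsQ) stop("bitsP must exceed bitsQ")
  if (bitsQ < 16) stop("bitsQ is too small")
  .withSeed(seed, {
    mrSeed <- sample.int(.Machine$integer.max, 1)
    q <- NULL
    for (i in seq_len(maxIter)) {
      cand <- .randomOddHex(bitsQ)
      if (.bnIsPrime(cand, .MR_ROUNDS, mrSeed + i)) { q <- cand; break }
    }
    if (is.null(q)) stop("setup-failure: no prime q found within budget")
    p <- NULL; r <- NULL
    for (i in seq_len(maxIter)) {
      rb <- randomBits(bitsP - bitsQ)
      rb[1] <- 1L
      rcand <- bitsToHex(rb)
      pcand <- .bnAdd(.bnMul(q, rcand), "1")
      if (.bnIsPrime(pcand, .MR_ROUNDS, mrSeed + 7L * i)) {
        p <- pcand; r <- rcand; break
      }
    }
    if (is.null(p)) stop("setup-failure: no prime p = q*r + 1 found within budget")
    g <- "1"
    while (.bnCmp(g, "1") == 0) {
      z <- .randomHexBelow(p, bitsP)
      g <- .bnModExp(z, r, p)
    }
    a <- "0"
    while (.bnCmp(a, "0") == 0) a <- .randomHexBelow(q, bitsQ)
    h <- .bnModExp(g, a, p)
    key <- new("CommitKey", p = p, q = q, g = g, h = h,
               bitsP = as.integer(bitsP), bitsQ = as.integer(bitsQ))
    if (retainTrapdoor) attr(key, "trapdoor") <- a
    key
  })
}

#' Digest identifying a commitment key
#' @param key a \linkS4class{CommitKey}.
#' @return 8-hex-digit string.
#' @export
keyDigest <- function(key) bitDigest(paste(key@p, key@q, key@g, key@h, sep = "|"))

#' Commit to a codeword under a witness
#'
#' phi = g^int(c) h^int(x) mod p with big-endian integer embeddings, and
#' delta = x XOR c. XOR (self-inverse) is used for the difference vector so
#' that the authentication identities close; see the package vignette.
#'
#' @param key a \linkS4class{CommitKey}.
#' @param codeword integer 0/1 vector of length n (a BCH codeword).
#' @param witness integer 0/1 vector of length n (here: the reference EEG
#'   code, zero-padded to n).
#' @return a \linkS4class{Commitment}.
#' @export
commitCode <- function(key, codeword, witness) {
  codeword <- as.integer(codeword); witness <- as.integer(witness)
  if (length(codeword) != length(witness))
    stop("codeword and witness must have the same length")
  chex <- bitsToHex(codeword); xhex <- bitsToHex(witness)
  if (.bnCmp(chex, key@q) >= 0 || .bnCmp(xhex, key@q) >= 0)
    stop("embedding exceeds subgroup order q; use larger bitsQ")
  phi <- .bnMulMod(.bnModExp(key@g, chex, key@p),
                   .bnModExp(key@h, xhex, key@p), key@p)
  new("Commitment", phi = phi, delta = xorBits(witness, codeword))
}

#' Open a commitment with an approximate witness
#'
#' Recovers c' = decode(witness' XOR delta); if decoding fails the opening is
#' rejected. Otherwise x'' = delta XOR c' and phi' = g^c' h^x'' mod p are
#' recomputed, and the embedded message is returned iff phi' equals the
#' committed phi. Rejection is a value (NULL), not an error.
#'
#' @param key a \linkS4class{CommitKey}.
#' @param com a \linkS4class{Commitment}.
#' @param witnessPrime integer 0/1 vector of length n, within Hamming
#'   distance t of the original witness for a successful opening.
#' @param codec the \linkS4class{BCHCode} used to form the codeword.
#' @return integer 0/1 message of length k, or NULL (REJECT).
#' @export
openCommitment <- function(key, com, witnessPrime, codec) {
  witnessPrime <- as.integer(witnessPrime)
  if (length(witnessPrime) != length(com@delta))
    stop("witness length does not match delta")
  cprime <- bchDecode(codec, xorBits(witnessPrime, com@delta))
  if (is.null(cprime)) return(NULL)
  xsec <- xorBits(com@delta, cprime)
  phi2 <- .bnMulMod(.bnModExp(key@g, bitsToHex(cprime), key@p),
                    .bnModExp(key@h, bitsToHex(xsec), key@p), key@p)
  if (.bnCmp(phi2, com@phi) != 0) return(NULL)
  extractMessage(codec, cprime)
}

#' Serialize / deserialize a commitment key as JSON
#' @param key a \linkS4class{CommitKey}.
#' @param path file path.
#' @return \code{readCommitKey} returns a \linkS4class{CommitKey}.
#' @export
writeCommitKey <- function(key, path) {
  jsonlite::write_json(list(p = key@p, q = key@q, g = key@g, h = key@h,
                            bits_p = key@bitsP, bits_q = key@bitsQ),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeCommitKey
#' @export
readCommitKey <- function(path) {
  o <- jsonlite::read_json(path)
  new("CommitKey", p = o$p, q = o$q, g = o$g, h = o$h,
      bitsP = as.integer(o$bits_p), bitsQ = as.integer(o$bits_q))
}

# ---- empirical security games ---------------------------------------------

#' Play the hiding game
#'
#' Per round: two random distinct k-bit messages are drawn, one is selected
#' at random and committed under a fresh uniform witness, and the guesser is
#' asked which message the commitment hides. Returns the empirical win rate;
#' a guesser with no advantage wins about half the rounds.
#'
#' @param key a \linkS4class{CommitKey}.
#' @param codec a \linkS4class{BCHCode}.
#' @param guesser function(key, commitment, m1, m2) returning 1 or 2.
#' @param trials number of rounds.
#' @param seed integer seed.
#' @return list with winRate, wins, trials.
#' @export
playHidingGame <- function(key, codec, guesser = guesserRandom, trials = 1000,
                           seed = 1) {
  if (trials < 1) stop("trials must be at least 1")
  .withSeed(seed, {
    wins <- 0L
    for (i in seq_len(trials)) {
      m1 <- randomBits(codec@k)
      repeat { m2 <- randomBits(codec@k); if (any(m1 != m2)) break }
      b <- sample(1:2, 1)
      com <- commitCode(key, bchEncode(codec, if (b == 1L) m1 else m2),
                        randomBits(codec@n))
      if (identical(as.integer(guesser(key, com, m1, m2)), b)) wins <- wins + 1L
    }
    list(winRate = wins / trials, wins = wins, trials = trials)
  })
}

#' Blind guesser for the hiding game
#' @param key,commitment,m1,m2 game inputs (ignored except for randomness).
#' @return 1 or 2.
#' @export
guesserRandom <- function(key, commitment, m1, m2) sample(1:2, 1)

#' Commitment-inspecting guesser for the hiding game
#'
#' A naive distinguisher that looks only at the committed value phi (parity
#' of its low hex digit against the parity of the candidate messages). Its
#' win rate is reported by the harness; against uniform witnesses it has no
#' advantage.
#'
#' @param key a \linkS4class{CommitKey}.
#' @param commitment a \linkS4class{Commitment}.
#' @param m1,m2 candidate messages.
#' @return 1 or 2.
#' @export
guesserPhiParity <- function(key, commitment, m1, m2) {
  low <- strtoi(substr(commitment@phi, nchar(commitment@phi), nchar(commitment@phi)), 16L)
  if (low %% 2L == sum(m1) %% 2L) 1L else 2L
}

#' Play the binding game
#'
#' The binder is asked for two openings of the same commitment value phi:
#' two (Commitment, witness) pairs sharing phi. The game opens both through
#' \code{openCommitment} and outputs 1 iff both open and the recovered
#' messages differ.
#'
#' @param key a \linkS4class{CommitKey}.
#' @param codec a \linkS4class{BCHCode}.
#' @param binder function(key, codec) returning NULL or a list with elements
#'   com1, w1, com2, w2.
#' @return 0 or 1.
#' @export
playBindingGame <- function(key, codec, binder) {
  out <- binder(key, codec)
  if (is.null(out)) return(0L)
  if (.bnCmp(out$com1@phi, out$com2@phi) != 0) return(0L)
  msg1 <- openCommitment(key, out$com1, out$w1, codec)
  msg2 <- openCommitment(key, out$com2, out$w2, codec)
  if (is.null(msg1) || is.null(msg2)) return(0L)
  if (identical(msg1, msg2)) return(0L)
  1L
}

#' Naive random binder
#'
#' Commits to a random message, then tries random second openings hoping to
#' collide with the same phi. With overwhelming probability it fails and the
#' binding game scores 0.
#'
#' @param attempts number of random second openings to try.
#' @param seed integer seed.
#' @return a binder function for \code{\link{playBindingGame}}.
#' @export
binderRandom <- function(attempts = 1000, seed = 1) {
  function(key, codec) {
    .withSeed(seed, {
      m1 <- randomBits(codec@k); x1 <- randomBits(codec@n)
      com1 <- commitCode(key, bchEncode(codec, m1), x1)
      for (i in seq_len(attempts)) {
        m2 <- randomBits(codec@k); x2 <- randomBits(codec@n)
        com2 <- commitCode(key, bchEncode(codec, m2), x2)
        if (.bnCmp(com1@phi, com2@phi) == 0 && any(m1 != m2))
          return(list(com1 = com1, w1 = x1, com2 = com2, w2 = x2))
      }
      NULL
    })
  }
}

#' Trapdoor binder
#'
#' Demonstrates that binding rests entirely on discarding a = log_g h: a
#' binder holding the trapdoor solves c1 + a x1 = c2 + a x2 (mod q) for x2
#' and equivocates the commitment. Requires a key generated with
#' \code{retainTrapdoor = TRUE}; returns NULL (binder loses) otherwise.
#'
#' @param maxTries retries until the solved x2 fits in n bits.
#' @param seed integer seed.
#' @return a binder function for \code{\link{playBindingGame}}.
#' @export
binderTrapdoor <- function(maxTries = 20000, seed = 1) {
  function(key, codec) {
    a <- attr(key, "trapdoor")
    if (is.null(a)) return(NULL)
    .withSeed(seed, {
      q <- key@q
      ainv <- .bnModExp(a, .bnSub(q, "2"), q) # Fermat inverse, q prime
      m1 <- randomBits(codec@k)
      c1 <- bchEncode(codec, m1)
      c1h <- bitsToHex(c1)
      for (i in seq_len(maxTries)) {
        # fresh second message each try: the solved x2 = x1 + (c1 - c2)/a
        # (mod q) must also land below 2^n to be a valid witness string
        repeat { m2 <- randomBits(codec@k); if (any(m1 != m2)) break }
        c2 <- bchEncode(codec, m2)
        c2h <- bitsToHex(c2)
        diff <- .bnMod(.bnSub(.bnAdd(c1h, q), c2h), q) # (c1 - c2) mod q
        shift <- .bnMulMod(diff, ainv, q)
        x1 <- randomBits(codec@n)
        x2h <- .bnMod(.bnAdd(bitsToHex(x1), shift), q)
        if (.bnBitLength(x2h) <= codec@n) {
          x2 <- hexToBits(x2h, codec@n)
          com1 <- commitCode(key, c1, x1)
          com2 <- new("Commitment", phi = com1@phi, delta = xorBits(x2, c2))
          return(list(com1 = com1, w1 = x1, com2 = com2, w2 = x2))
        }
      }
      NULL
    })
  }
}
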