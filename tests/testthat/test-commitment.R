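# The prime-order subgroup commitment: setup invariants, exact small-number
# oracles, correctness, algebraic properties and the hiding/binding games.

test_that("setup produces a valid subgroup key deterministically", {
  key <- toyKey()
  one <- "1"
  expect_identical(bn("Mod")(bn("Sub")(key@p, one), key@q), "0") # q | p - 1
  expect_identical(bn("ModExp")(key@g, key@q, key@p), one)
  expect_identical(bn("ModExp")(key@h, key@q, key@p), one)
  expect_false(key@g == one || key@h == one)
  key2 <- commitSetup(bitsP = 40, bitsQ = 24, seed = 424242)
  expect_identical(key2@p, key@p)
  expect_identical(key2@h, key@h)
  expect_error(commitSetup(bitsP = 24, bitsQ = 40), "exceed")
})

test_that("commitment value matches an exact modular-exponentiation oracle", {
  key <- tinyKey() # p = 23, q = 11, g = 2, h = 8
  # c = 5 = 101b, x = 7 = 111b: phi = 2^5 * 8^7 mod 23
  com <- commitCode(key, c(1L, 0L, 1L), c(1L, 1L, 1L))
  oracle <- (2^5 * 8^7) %% 23 # exact in doubles (8^7 = 2^21)
  expect_identical(com@phi, sprintf("%x", oracle))
  expect_identical(com@delta, c(0L, 1L, 0L)) # 111 XOR 101
  # identity exponents
  com0 <- commitCode(key, c(0L, 0L, 0L), c(0L, 0L, 0L))
  expect_identical(com0@phi, "1")
  expect_identical(com0@delta, c(0L, 0L, 0L))
  # determinism
  expect_identical(commitCode(key, c(1L, 0L, 1L), c(1L, 1L, 1L))@phi, com@phi)
  expect_error(commitCode(key, c(1L, 0L), c(1L, 1L, 1L)), "same length")
})

test_that("every commitment lies in the order-q subgroup", {
  key <- toyKey(); codec <- toyCodec()
  set.seed(61)
  for (i in 1:25) {
    com <- commitCode(key, bchEncode(codec, randomBits(codec@k)),
                      randomBits(codec@n))
    expect_identical(bn("ModExp")(com@phi, key@q, key@p), "1")
  }
})

test_that("the commitment is homomorphic in the integer-embedded exponents", {
  key <- tinyKey()
  # (c1, x1) = (3, 2), (c2, x2) = (4, 5): sums 7, 7 stay below q = 11
  phi1 <- commitCode(key, c(0L, 1L, 1L), c(0L, 1L, 0L))@phi
  phi2 <- commitCode(key, c(1L, 0L, 0L), c(1L, 0L, 1L))@phi
  phiSum <- commitCode(key, c(1L, 1L, 1L), c(1L, 1L, 1L))@phi
  expect_identical(bn("MulMod")(phi1, phi2, key@p), phiSum)
})

test_that("open(commit(m)) recovers m for 200 seeded pairs at default size", {
  key <- defaultKey(); codec <- defaultBCHCode()
  set.seed(71)
  ok <- TRUE
  for (i in 1:200) {
    m <- randomBits(codec@k); x <- randomBits(codec@n)
    com <- commitCode(key, bchEncode(codec, m), x)
    ok <- ok && identical(openCommitment(key, com, x, codec), m)
  }
  expect_true(ok)
})

test_that("opening tolerates up to t witness errors and detects tampering", {
  key <- toyKey(); codec <- toyCodec()
  set.seed(81)
  for (i in 1:30) {
    m <- randomBits(codec@k); x <- randomBits(codec@n)
    com <- commitCode(key, bchEncode(codec, m), x)
    expect_identical(openCommitment(key, com, flipBits(x, sample(0:2, 1)),
                                    codec), m)
  }
  # tampering one delta bit with the true witness must reject
  m <- randomBits(codec@k); x <- randomBits(codec@n)
  com <- commitCode(key, bchEncode(codec, m), x)
  tampered <- new("Commitment", phi = com@phi,
                  delta = flipBits(com@delta, 1, positions = 4))
  res <- openCommitment(key, tampered, x, codec)
  expect_false(identical(res, m))
})

test_that("blind strategies win the hiding game about half the time", {
  key <- toyKey(); codec <- toyCodec()
  g1 <- playHidingGame(key, codec, guesserRandom, trials = 10000, seed = 5)
  expect_lt(abs(g1$winRate - 0.5), 3 * sqrt(0.25 / 10000)) # 3 standard errors
  ignoreAll <- function(key, commitment, m1, m2) 1L
  g2 <- playHidingGame(key, codec, ignoreAll, trials = 2000, seed = 6)
  expect_lt(abs(g2$winRate - 0.5), 3 * sqrt(0.25 / 2000))
  # a phi-inspecting guesser is measured and reported, not asserted
  g3 <- playHidingGame(key, codec, guesserPhiParity, trials = 2000, seed = 7)
  expect_true(g3$winRate >= 0 && g3$winRate <= 1)
})

test_that("binding holds for naive binders and breaks only with the trapdoor", {
  key <- toyKey(); codec <- toyCodec()
  expect_equal(playBindingGame(key, codec, binderRandom(1000, seed = 8)), 0L)
  # a binder that reuses one message never wins by definition
  sameMsg <- function(key, codec) {
    m <- rep(0L, codec@k); x <- randomBits(codec@n)
    com <- commitCode(key, bchEncode(codec, m), x)
    list(com1 = com, w1 = x, com2 = com, w2 = x)
  }
  set.seed(9)
  expect_equal(playBindingGame(key, codec, sameMsg), 0L)
  # holding a = log_g h breaks binding: expected leakage when a is retained
  keyTrap <- commitSetup(bitsP = 40, bitsQ = 24, seed = 424242,
                         retainTrapdoor = TRUE)
  expect_equal(playBindingGame(keyTrap, codec, binderTrapdoor(seed = 10)), 1L)
  # the same binder loses against a key whose trapdoor was discarded
  expect_equal(playBindingGame(key, codec, binderTrapdoor(seed = 10)), 0L)
})

test_that("keys serialize to JSON and back", {
  key <- toyKey()
  path <- withr::local_tempfile(fileext = ".json")
  writeCommitKey(key, path)
  key2 <- readCommitKey(path)
  expect_identical(key2@p, key@p)
  expect_identical(key2@h, key@h)
  expect_identical(keyDigest(key2), keyDigest(key))
})
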