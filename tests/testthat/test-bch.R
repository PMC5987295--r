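# BCH encoding/decoding: systematic structure, exhaustive bounded-distance
# correction for the (15, 7, 2) code, and the zero-padding plumbing.

test_that("systematic encoding is linear and divisible by the generator", {
  spec <- toyCodec() # (15, 7, 2)
  expect_identical(bchEncode(spec, rep(0L, 7)), rep(0L, 15))
  set.seed(11)
  for (i in 1:20) {
    m1 <- randomBits(spec@k); m2 <- randomBits(spec@k)
    c1 <- bchEncode(spec, m1); c2 <- bchEncode(spec, m2)
    expect_identical(polyModGF2(c1, spec@generator), 0L)
    expect_true(all(bchSyndromes(spec, xorBits(c1, c2)) == 0L)) # linearity
    # systematic positions carry the message
    expect_identical(c1[(spec@n - spec@k + 1):spec@n], m1)
    expect_identical(extractMessage(spec, c1), m1)
  }
  expect_error(bchEncode(spec, rep(0L, 6)), "exactly k")
  expect_error(extractMessage(spec, flipBits(bchEncode(spec, rep(0L, 7)), 1,
                                             positions = 3)),
               "not a valid codeword")
})

test_that("all 1- and 2-bit errors are corrected exhaustively for (15, 7, 2)", {
  spec <- toyCodec()
  msgs <- as.matrix(expand.grid(rep(list(0:1), 7)))
  patterns <- c(lapply(1:15, function(i) i),
                combn(15, 2, simplify = FALSE))
  allOK <- TRUE
  for (r in seq_len(nrow(msgs))) {
    cw <- bchEncode(spec, msgs[r, ])
    ok <- identical(bchDecode(spec, cw), cw) && # zero-error case
      all(vapply(patterns, function(pos) {
        identical(bchDecode(spec, flipBits(cw, length(pos), positions = pos)),
                  cw)
      }, logical(1)))
    allOK <- allOK && ok
  }
  expect_true(allOK) # 128 codewords x (15 + 105) error patterns
})

test_that("words beyond every decoding sphere are declared invalid", {
  spec <- toyCodec()
  msgs <- as.matrix(expand.grid(rep(list(0:1), 7)))
  cws <- t(apply(msgs, 1, function(m) bchEncode(spec, m)))
  # find a weight-3 word with distance >= 3 from all 128 codewords
  found <- NULL
  for (pos in combn(15, 3, simplify = FALSE)) {
    w <- rep(0L, 15); w[pos] <- 1L
    dmin <- min(rowSums(cws != matrix(w, nrow(cws), 15, byrow = TRUE)))
    if (dmin >= 3) { found <- w; break }
  }
  expect_false(is.null(found))
  expect_null(bchDecode(spec, found))
})

test_that("decoding success degrades beyond the design capability", {
  spec <- toyCodec()
  set.seed(21)
  cw <- bchEncode(spec, randomBits(spec@k))
  res <- vapply(combn(15, 3, simplify = FALSE), function(pos) {
    identical(bchDecode(spec, flipBits(cw, 3, positions = pos)), cw)
  }, logical(1))
  expect_lt(mean(res), 1) # weight t + 1 is not always corrected
})

test_that("the default (511, 67, 87) code corrects 87 errors and not 88+", {
  spec <- defaultBCHCode()
  expect_equal(c(spec@n, spec@k, spec@t), c(511L, 67L, 87L))
  x511 <- c(1L, rep(0L, 510), 1L)
  expect_identical(polyModGF2(x511, spec@generator), 0L)
  set.seed(31)
  msg <- randomBits(spec@k)
  cw <- bchEncode(spec, msg)
  for (i in 1:25) {
    ne <- sample(0:87, 1)
    expect_identical(bchDecode(spec, flipBits(cw, ne)), cw)
  }
  miscorrected <- 0L
  for (i in 1:25) {
    dec <- bchDecode(spec, flipBits(cw, 88))
    if (!is.null(dec) && identical(dec, cw)) miscorrected <- miscorrected + 1L
  }
  expect_equal(miscorrected, 0L)
  expect_identical(extractMessage(spec, cw), msg)
})

test_that("random messages round-trip through encode/extract", {
  spec <- toyCodec()
  set.seed(41)
  for (i in 1:100) {
    m <- randomBits(spec@k)
    expect_identical(extractMessage(spec, bchEncode(spec, m)), m)
  }
})

test_that("padding is a fixed-tail zero embedding compatible with XOR", {
  set.seed(51)
  x <- randomBits(400); y <- randomBits(400)
  px <- padCode(x, 511)
  expect_length(px, 511)
  expect_identical(unpadCode(px, 400), x)
  expect_true(all(px[401:511] == 0L))
  expect_identical(xorBits(padCode(x, 511), padCode(y, 511)),
                   padCode(xorBits(x, y), 511))
  expect_error(padCode(randomBits(600), 511), "longer")
})

test_that("BCH parameters serialize to JSON and back", {
  spec <- toyCodec()
  path <- withr::local_tempfile(fileext = ".json")
  writeBCHCode(spec, path)
  spec2 <- readBCHCode(path)
  expect_identical(spec2@generator, spec@generator)
  expect_equal(c(spec2@n, spec2@k, spec2@t), c(spec@n, spec@k, spec@t))
})
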