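# Enrolment / authentication: completeness within the correction radius,
# rejection far outside it, and the no-secret-at-rest property of templates.

test_that("enrolment binds a recoverable key and stores no secrets", {
  key <- defaultKey(); codec <- defaultBCHCode()
  set.seed(91)
  code <- randomBits(400)
  en <- enrolCode(code, key, codec, seed = 17, subjectLabel = "alice")
  expect_length(en$kappa, codec@k)
  # algebraic identity at zero error: delta XOR x_ref is the codeword
  xref <- padCode(code, codec@n)
  cw <- xorBits(en$template@delta, xref)
  expect_identical(extractMessage(codec, bchDecode(codec, cw)), en$kappa)
  # different key seeds give different keys and commitment values
  en2 <- enrolCode(code, key, codec, seed = 18)
  expect_false(identical(en2$kappa, en$kappa))
  expect_false(identical(en2$template@phi, en$template@phi))
  # serialized template contains neither the key nor the reference code
  path <- withr::local_tempfile(fileext = ".json")
  writeTemplate(en$template, path)
  json <- paste(readLines(path, warn = FALSE), collapse = "")
  expect_false(grepl(bitsToHex(en$kappa), json, fixed = TRUE))
  expect_false(grepl(bitsToHex(xref), json, fixed = TRUE))
  expect_false(grepl(paste(en$kappa, collapse = ""), json, fixed = TRUE))
  # and round-trips losslessly
  back <- readTemplate(path)
  expect_identical(back@phi, en$template@phi)
  expect_identical(back@delta, en$template@delta)
  expect_identical(back@subjectLabel, "alice")
})

test_that("authentication completes at distance <= t and releases the key", {
  key <- defaultKey(); codec <- defaultBCHCode()
  set.seed(92)
  code <- randomBits(400)
  en <- enrolCode(code, key, codec, seed = 19)
  r0 <- authenticateCode(code, en$template, key, codec)
  expect_true(isAccepted(r0))
  expect_identical(releasedKey(r0), en$kappa)
  for (i in 1:30) {
    probe <- flipBits(code, sample(0:codec@t, 1))
    r <- authenticateCode(probe, en$template, key, codec)
    expect_true(isAccepted(r))
    expect_identical(releasedKey(r), en$kappa)
  }
  # the complement (400 errors) is far outside every decoding sphere
  rc <- authenticateCode(1L - code, en$template, key, codec)
  expect_false(isAccepted(rc))
  expect_length(releasedKey(rc), 0L)
})

test_that("completeness is exhaustive for a small code", {
  key <- toyKey(); codec <- toyCodec()
  set.seed(93)
  code <- randomBits(9) # 3-channel biometric code, padded to n = 15
  en <- enrolCode(code, key, codec, seed = 20)
  patterns <- c(list(integer(0)), as.list(1:9), combn(9, 2, simplify = FALSE))
  ok <- vapply(patterns, function(pos) {
    probe <- flipBits(code, length(pos), positions = pos)
    r <- authenticateCode(probe, en$template, key, codec)
    isAccepted(r) && identical(releasedKey(r), en$kappa)
  }, logical(1))
  expect_true(all(ok)) # every error pattern of weight <= t accepted
})

test_that("independent random probes are never accepted", {
  key <- defaultKey(); codec <- defaultBCHCode()
  set.seed(94)
  en <- enrolCode(randomBits(400), key, codec, seed = 21)
  accepted <- 0L
  for (i in 1:2000) {
    if (isAccepted(authenticateCode(randomBits(400), en$template, key, codec)))
      accepted <- accepted + 1L
  }
  expect_equal(accepted, 0L)
})

test_that("mismatched parameters are refused loudly", {
  key <- defaultKey(); codec <- defaultBCHCode()
  set.seed(95)
  en <- enrolCode(randomBits(400), key, codec, seed = 22)
  expect_error(authenticateCode(randomBits(400), en$template, key, toyCodec()),
               "codec does not match")
  expect_error(authenticateCode(randomBits(400), en$template, toyKey(), codec),
               "key does not match")
})

test_that("recording-level enrolment and majority-vote combination work", {
  key <- defaultKey(); codec <- defaultBCHCode()
  subj <- makeSubject(20, seed = 44)
  recs <- lapply(1:3, function(i) sampleRecording(subj, 400, 0.05, seed = i))
  en1 <- enrol(recs[[1]], key, codec, seed = 23)
  r <- authenticate(recs[[1]], en1$template, key, codec)
  expect_true(isAccepted(r))
  expect_identical(releasedKey(r), en1$kappa)
  expect_error(enrol(recs, key, codec, seed = 24), "majorityVote")
  enM <- enrol(recs, key, codec, seed = 24, majorityVote = TRUE)
  rM <- authenticate(recs[[2]], enM$template, key, codec)
  expect_true(isAccepted(rM)) # same-subject sample within the radius
})
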