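# Shared fixtures, built once per test run. All randomness is seeded.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

toyCodec <- function() fixture("toyCodec", function() bchCode(4, 2))

toyKey <- function() fixture("toyKey", function() {
  commitSetup(bitsP = 40, bitsQ = 24, seed = 424242)
})

# hand-checkable key: p = 23, q = 11, g = 2 (2^11 = 2048 = 89*23 + 1), h = 2^3
tinyKey <- function() new("CommitKey", p = "17", q = "b", g = "2", h = "8",
                          bitsP = 5L, bitsQ = 4L)

defaultKey <- function() fixture("defaultKey", function() {
  commitSetup(bitsP = 576, bitsQ = 520, seed = 20240901)
})

lowNoiseCohort <- function() fixture("lowNoiseCohort", function() {
  makeCohort(cohortConfig(42, 2, sessionNoise = 0.05, masterSeed = 101))
})

lowNoiseCodes <- function() fixture("lowNoiseCodes", function() {
  encodeCohort(lowNoiseCohort())
})

flipBits <- function(bits, k, positions = NULL) {
  if (is.null(positions)) positions <- sample(length(bits), k)
  bits[positions] <- 1L - bits[positions]
  bits
}

# slow reference multiplication in GF(2^m): polynomial product reduced mod
# the primitive polynomial, one bit at a time (independent of the tables)
slowGfMul <- function(a, b, m, prim) {
  r <- 0L
  for (i in 0:(m - 1)) {
    if (bitwAnd(b, bitwShiftL(1L, i)) != 0L) {
      sh <- a
      for (j in seq_len(i)) {
        sh <- bitwShiftL(sh, 1L)
        if (sh >= 2L^m) sh <- bitwXor(sh, prim)
      }
      r <- bitwXor(r, sh)
    }
  }
  r
}

bn <- function(name) get(paste0(".bn", name), envir = asNamespace("eegcommit"))
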