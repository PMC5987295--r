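---
title: "Binding cryptographic keys to EEG: the model behind eegcommit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding cryptographic keys to EEG: the model behind eegcommit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegcommit)
```

## The problem

Biometric signals are noisy: two EEG sessions of the same person never yield
identical feature vectors, so a biometric can neither be hashed like a
password nor stored in the clear. The fuzzy-commitment construction resolves
this by binding a *random* cryptographic key to the biometric through an
error-correcting code: what is stored reveals (computationally) neither the
key nor the biometric, yet any re-presentation of the biometric within the
code's correction radius releases the exact key. `eegcommit` implements this
construction end-to-end for multichannel EEG, together with the evaluation
machinery needed to characterize it as a biometric system.

## From recording to binary template

A recording is a channels × samples matrix; 20 channels in the 10--20
layout and 1000 samples at 256 Hz are the default study scale. The encoding
is deliberately minimal:

1. **Covariance.** `covarianceMatrix()` computes the channel covariance with
   the population divisor (the number of time samples `T`). The spatial
   covariance is the only feature the pipeline consumes; its divisor is
   irrelevant downstream because the next two steps normalize scale away.
2. **Column z-scores.** `zscoreColumns()` standardizes each column of the
   covariance matrix with the sample standard deviation (divisor N − 1).
   A zero-variance column is mapped to zeros rather than dividing by zero.
   Z-scoring is column-wise, so the binarized matrix has no symmetry
   guarantee even though the covariance is symmetric — nothing downstream
   assumes symmetry.
3. **Min--max normalization** over the whole matrix into [0, 1]; a constant
   matrix maps to all zeros (any constant is admissible; zero is the
   conventional choice).
4. **Thresholding** at 0.5, with equality mapping to 1, and row-major
   flattening into a bit vector of length channels² — 400 bits for 20
   channels. Row-major order is part of the template format and must be
   fixed for interoperability.

The composition is deterministic and invariant to multiplying all channels
by a positive constant, which makes the code robust to global gain
differences between amplifiers. It is *not* invariant to per-channel gain
differences, re-referencing, or filtering; no spectral features, artifact
rejection or channel selection are attempted.

## The error-correcting layer

The key is protected by a binary BCH code over GF(2^m). `buildField()`
tabulates the powers of a primitive element (default primitive polynomials
are standard low-weight choices, e.g. x⁹ + x⁴ + 1 for m = 9);
`bchCode()` forms the generator polynomial as the least common multiple of
the minimal polynomials of α¹ … α^2t, giving designed distance 2t + 1, and
derives k = n − deg(g). Encoding is systematic (message in the high-degree
positions); decoding is bounded-distance via syndromes, Berlekamp--Massey
and Chien search — the textbook O(n·t) pipeline, implemented in C++ because
the evaluation suite decodes tens of thousands of words. A word outside
every decoding sphere is a *value* (`NULL`), not an error: rejection is a
legitimate outcome of authentication.

**Default parameters.** `defaultBCHCode()` is m = 9, t = 87: n = 511,
k = 67 (generator degree 444). The designed capability t = 87 realizes the
empirically motivated error budget for 400-bit EEG codes: on real data the
genuine and impostor bit-error distributions cross at about 87 of 400 bits,
so the correction radius is set to tolerate exactly that much within-subject
noise. Both m and t are configurable; `bchCode()` refuses capabilities that
leave no message bits.

Two consequences are worth stating plainly. First, a 511-bit code cannot
carry a 400-bit key at this correction level: the rate--distance tradeoff
caps the key at k = 67 bits for t = 87, and the package reports the true k
of whatever code is configured. Second, the 400-bit EEG code is
**zero-padded** to 511 positions rather than the code being shortened by 111
positions: the padding tail is fixed to zero on both enrolment and probe
codes, so it never carries errors and the full capability t is spent on the
biometric positions. Shortening was rejected because removing 111 positions
is incompatible with the low-rate generator needed for t ≥ 87.

## The commitment layer

`commitSetup()` generates primes q (default 520 bits) and p = q·r + 1
(default ~576 bits), a generator g of the order-q subgroup of Z_p*, and
h = g^a with the exponent a discarded. Bit strings embed as exponents
big-endian, which is why q must exceed 2^n (hence ≥ 512 bits for n = 511):
the embedding is then injective and commitment equality is meaningful.
Enrolment stores

- φ = g^c · h^x_ref (mod p) — the commitment value, and
- δ = x_ref ⊕ c — the difference vector (the "sketch").

The difference vector uses XOR, not arithmetic difference: XOR is
self-inverse, so the authentication identities
ĉ = x_test ⊕ δ = c ⊕ (x_test ⊕ x_ref) and x′ = δ ⊕ c′ close exactly; an
arithmetic difference would not commute with the bitwise error model.
Similarly, the commitment is to the *codeword* c (not the raw message): the
verifier recomputes φ′ = g^c′ · h^(δ⊕c′) after decoding and compares, then
recovers κ as the systematic part of c′.

Security is treated empirically, not theorem-style. `playHidingGame()` runs
the two-message distinguishing game (fresh uniform witness per round) and
reports win rates; `playBindingGame()` asks a binder for two openings of one
φ. The package demonstrates constructively that binding rests on discarding
a: `binderTrapdoor()` solves c₁ + a·x₁ ≡ c₂ + a·x₂ (mod q) and wins
whenever a is retained (`commitSetup(retainTrapdoor = TRUE)`), and loses
otherwise. One honest caveat, measured but not asserted away: when the
witness is a *biometric* rather than a uniform string, δ = x ⊕ c is not
uniform, so the scheme's hiding is imperfect in a way the abstract analysis
ignores. The harness can measure distinguishers; the package does not claim
perfect hiding. The arithmetic is not constant-time — this is a research
artifact, not a hardened implementation.

## The synthetic cohort generator

No dataset accompanies the method, so the generator emulates the *study
structure*: S subjects × r recordings, 20 channels × 1000 samples at 256 Hz
by default. Each subject is a base covariance from a random factor model
(A·Aᵀ/C + 0.05·I), which is positive-definite by construction and gives
each subject a distinct binarized pattern. A session perturbs the base with
seeded symmetric noise of scale `sessionNoise` (eigenvalues clipped at 1e-6
to stay positive-definite) and draws a zero-mean Gaussian recording. The
whole cohort is a pure function of its configuration including the master
seed. Per-subject sample counts are uniform by default (a vector override is
accepted); a real study's uneven allocation is not modeled.

`sessionNoise` is the one parameter that matters. Its default 0.1 (relative
to the unit-scale base diagonal) produces intra-subject code distances
around 30 of 400 bits against inter-subject distances around 60--70 — i.e.
clearly separated means with slight tail overlap, which is what realistic
biometric score distributions look like. "Low-noise" experiments in the
tests use 0.05, at which the two distributions separate almost completely
(identification CCR ≈ 0.99, EER < 0.01 on a 42-subject cohort).

What the generator does **not** emulate: neurophysiological spectra
(alpha/beta band structure), artifacts (blinks, EMG), nonstationarity, or
electrode displacement between sessions. Consequently, passing tests
demonstrate that the *pipeline's* discriminative plumbing is correct — codes
separate when covariances separate, accuracy degrades monotonically with
session noise — not that real EEG achieves any particular error rate.

A second structural caveat: the synthetic inter-subject distances (~60 bits)
are *below* the default correction radius t = 87, so under the default codec
a synthetic impostor's recording would open a genuine template. On the
method's real data the impostor distribution sits mostly above 87 — that is
exactly why 87 was chosen there. The soundness property the package asserts
uses independent random probes (expected distance ~200 bits, 0 acceptances
in 10,000 trials); demonstrations that need synthetic impostors rejected
(e.g. the command-line round trip) use a codec with t = 25, which sits
between the synthetic intra (~20--30) and inter (~60) distances.

## Evaluation conventions

- **Acceptance convention:** accept iff normalized distance ≤ threshold, so
  FAR is non-decreasing and FRR non-increasing in the threshold.
- **Threshold grid:** all distinct observed scores plus the endpoints 0 and
  1 — exact step-function evaluation, no binning error.
- **EER:** reported as (FAR + FRR)/2 at T* = argmin |FAR − FRR|, ties broken
  toward the smallest threshold; exact equality rarely occurs on a finite
  grid.
- **Identification (`scenario1`):** leave-one-out nearest-template by
  normalized Hamming distance, ties toward the lowest subject index;
  subjects with one sample are excluded with a warning. With all-identical
  codes this collapses to chance level 1/S deterministically.
- **Verification (`scenario2`):** per-subject half split; the operating
  threshold is the EER point of the enrolment-half scores shifted to the
  midpoint of the tie region (on a step-function grid the argmin lands
  exactly on an observed genuine score, which would split boundary probes
  arbitrarily); positives are bootstrap-oversampled to balance the classes.
- **Error tolerance (`errorToleranceBits`):** per-bit-count histograms of
  genuine and impostor raw distances; returns the largest count d such that
  the genuine density ≥ impostor density at every count ≤ d. For fully
  separated distributions this lands at or beyond the largest genuine
  distance.
- **Fisher-Z pooling:** accuracies are passed through atanh as if they were
  correlations (clipped into (−1 + 1e-6, 1 − 1e-6)); the mean is
  back-transformed with tanh, the sd reported in transformed space. Applying
  a correlation transform to accuracies is methodologically idiosyncratic
  but mirrors how such pooling is reported in this literature.
- **McNemar:** Yates-corrected (|b − c| − 1)²/(b + c), 0 when b + c = 0,
  compared against qchisq(0.95, 1) ≈ 3.8415.

## Problem sizes in the shipped tests

The suite exercises: exhaustive correction of all ≤ 2-bit error patterns
for the (15, 7, 2) code (128 codewords × 120 patterns); randomized 0--87-bit
correction at (511, 67, 87); 200 commit/open round trips at the full
520-bit-q parameters; 10,000-probe soundness runs; 10,000-round hiding
games at toy parameters; and 42-subject cohorts with 2--4 recordings each.
These sizes keep the whole suite under a minute on one core while leaving
every claim exercised at, or exhaustively below, its operational scale.

## Known limitations

- EDF import is not provided; recordings are CSV (or constructed in R).
- Single-recording enrolment is the default (per-bit majority voting over
  several recordings is available behind `majorityVote = TRUE`).
- The key length at the default parameters is 67 bits — adequate for a
  research artifact, short for a modern credential; raising it requires
  lowering t or lengthening the code.
- Security properties are demonstrated by executable games, not proofs, and
  the implementation makes no side-channel claims.
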