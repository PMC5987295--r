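Package: eegcommit
Title: EEG Biometric Cryptosystem via Fuzzy Commitment and BCH Codes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A key-binding biometric cryptosystem for multichannel EEG.
    Recordings are encoded into fixed-length binary templates by thresholding
    normalized z-scores of the channel covariance matrix (400 bits for 20
    channels). A random cryptographic key is bound to the template through a
    fuzzy commitment: the key is encoded with a binary BCH code over GF(2^m),
    XOR-masked by the template, and committed with a discrete-logarithm
    commitment over a prime-order subgroup. Authentication re-presents a noisy
    template, corrects up to t bit errors by bounded-distance BCH decoding
    (Berlekamp-Massey and Chien search), and releases the key only if the
    recomputed commitment matches. Includes a synthetic multi-subject EEG
    cohort generator, biometric evaluation (FAR/FRR/EER/CCR/AUC, genuine and
    impostor Hamming-distance distributions, identification and verification
    scenarios, McNemar test, Fisher-Z pooling), and empirical hiding/binding
    game harnesses for the commitment.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    MASS,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
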