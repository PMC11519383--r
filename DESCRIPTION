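Package: fibralign
Title: Collagen Fiber Alignment and Wound-Healing Kinetics from Trichrome
    Histology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies collagen fiber organisation in Masson's
    trichrome-stained skin sections and the kinetics of wound closure.
    Collagen is isolated in CIELAB colour space (the a* channel
    superimposed onto the rectified negative b* channel), enhanced to a
    grayscale map with an exact-zero background, and analysed in the
    Fourier domain to yield a 0-1 alignment coefficient (energy-weighted
    circular resultant on doubled angles), a dominant fiber orientation,
    and a pixel-area density fraction. Companion tools simulate
    trichrome-like fiber fields with known orientation ground truth, fit
    one-phase exponential decay models to wound-area time series, compute
    wound contraction and closure percentages, and run paired
    t-test/Pearson group comparisons over batch manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    EBImage,
    minpack.lm,
    jsonlite,
    rlang,
    stats,
    grDevices,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
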