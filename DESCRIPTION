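Package: specmatch
Title: Window-Based Mass-Spectral Library Matching with a Variance-Scaled Metametric
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Identifies chemical compounds in electron-ionization mass spectra by
    reducing a query spectrum onto each reference compound's peak positions with a
    window function, scoring the reduced intensity distribution against the reference
    with four statistical distances (Kullback-Leibler, Bhattacharyya, Hellinger,
    cosine), and fusing them into a single variance-scaled metametric used to rank a
    plain-text spectral library. Includes iterative sigma-clipping background removal
    for profile spectra, a synthetic noisy-mixture generator, and a Monte-Carlo
    identification benchmark scored by top-K accuracy, mean reciprocal rank, and
    mean rank.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
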