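Package: sygyt
Title: Vocal Tract Modeling and Spectral Analysis of Biphonic Overtone Singing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the acoustics of Sygyt-style Tuvan throat
    singing with a linear source/filter framework. Converts traced midsagittal
    vocal-tract profiles into centerlines, cross-distance functions and area
    functions; computes lossy transmission-line frequency responses with
    yielding-wall, viscous, heat-conduction and lip-radiation losses; extracts
    formants and acoustic sensitivity functions; iteratively perturbs an area
    function until two formants merge onto a target overtone (the "focused
    state"); synthesizes normal and biphonic song from a harmonic glottal
    source; and quantifies focus in audio via spectrograms, harmonic tracking,
    a band energy-ratio statistic and transition detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
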