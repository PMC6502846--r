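Package: mackin
Title: Kinetics of Membrane Attack Complex Pore Assembly from Time-Lapse AFM Movies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for single-molecule time-lapse atomic force
    microscopy (AFM) movies of membrane attack complex (MAC) pore assembly.
    Provides a synthetic AFM movie generator with known assembly kinetics;
    image conditioning (plane levelling, line-by-line flattening, Gaussian
    smoothing); pore detection by normalized cross-correlation template
    matching with greedy track linking and gap closing; per-pore average
    height traces with Savitzky-Golay smoothing and tanh sigmoid fits of the
    oligomerization transition; and a two-rate kinetic model separating slow
    C9 initiation from fast sequential C9 oligomerization, including the
    appearance-curve fit, rate-constant conversion, and the linear birth
    chain occupancy distribution with an absorbing completed-pore state.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    signal,
    minpack.lm,
    deSolve,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
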