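Package: spinprobe
Title: Analysis of Nitroxide Spin-Label CW-ESR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for continuous-wave electron spin resonance (CW-ESR)
    spectra of nitroxide spin labels: simulation of fast-motion three-line
    spectra, ordered axial powder patterns and two-component mixtures with
    known ground truth; extraction of line positions, peak-to-peak widths and
    hyperfine splittings from first-derivative spectra; computation of the
    order parameter S, rotational correlation time tau_C, empirical mobility
    (inverse central linewidth) and polarity (isotropic hyperfine coupling);
    non-negative least-squares unmixing of mobile and immobilized spectral
    components; and control-versus-treated comparison reports for lipid and
    protein spin probes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    pracma,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
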