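Package: lightfieldHSI
Title: Simulation, Reconstruction and Spectral Analysis for Lenslet
    Lightfield Hyperspectral Imaging
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A desk-scale model of a snapshot lightfield hyperspectral
    imaging chain of the kind used for intra-operative tissue imaging.
    Provides a forward simulator for a 66-lenslet camera with per-lenslet
    Gaussian band-pass filters (FWHM 10 nm, 350-1000 nm), per-lenslet
    parallax and a 12-bit sensor; white/dark reference correction and
    Tikhonov-regularised spectral inversion from 66 lenslet measurements
    to a 155-band reflectance hypercube; colorimetrically faithful sRGB
    rendering via CIEXYZ with CIEDE2000 validation against reference
    spectra; and mask-driven region-of-interest spectral extraction with
    L1 normalisation and specular/saturation rejection. Includes synthetic
    ColorChecker-like and tissue-like phantom scenes with ground truth,
    ENVI cube I/O, and a small pipeline CLI.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
biocViews: Software, Spectroscopy, Visualization, Preprocessing
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'wavelength.R'
    'scenes.R'
    'camera.R'
    'reconstruction.R'
    'colorimetry.R'
    'analysis.R'
    'envi.R'
    'io.R'
    'experiment.R'
    'cli.R'
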