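Package: mosaicHSI
Title: Snapshot-Mosaic Hyperspectral Image Reconstruction, Demosaicing
    and Validation
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Processing toolkit for snapshot-mosaic hyperspectral cameras
    (spectrally resolved detector arrays) as used in laparoscopic and
    endoscopic imaging. Reconstructs hypercubes from raw mosaic sensor
    frames, performs white/dark reflectance calibration with glare
    clipping, removes the periodic filter-array pattern from
    full-resolution frames by three demosaicing methods (white-reference
    calibration, Fourier low-pass notch filtering, and filter-kernel
    convolution), quantifies spatial resolution with sine-fitted
    Michelson contrast against USAF-1951 target geometry, validates
    spectral fidelity against reference reflectance curves via percent
    RMSE, registers dual-camera hypercubes with control-point affine
    transforms, and renders pseudo-RGB images by nearest-band selection.
    Includes a forward simulator of mosaic acquisition (filter bank,
    illuminant, dark level, shot and read noise) so every stage is
    testable without hardware.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tiff,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils-internal.R'
    'sensor-model.R'
    'formats-io.R'
    'reconstruction.R'
    'demosaic.R'
    'resolution.R'
    'spectral-validation.R'
    'registration.R'
    'render.R'
    'srda-sim.R'
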