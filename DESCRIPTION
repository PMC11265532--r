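Package: hexdemosaic
Title: Residual CNN Demosaicing for Hexachromatic Color-NIR Image Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Demosaicing toolkit for single-chip hexachromatic image sensors
    that combine vertically stacked photodiodes with a checkerboard of
    visible-pass and near-infrared-pass pixelated filters, as used in
    fluorescence image-guided surgery. Models the checkerboard sampling
    geometry, implements the one-dimensional bilinear interpolation baseline,
    and provides a deep residual convolutional network (SELU activations,
    batch normalization, MSRA initialization, Adam optimization) that learns
    the high-frequency residual between the bilinear estimate and the full
    resolution image. Includes a four-metric evaluation protocol (per-channel
    PSNR and MSE, 95th-percentile DSSIM, 95th-percentile colour difference),
    Fourier-domain reconstruction analysis, a synthetic scene generator with
    vessel-like curvilinear structures, TIFF/PNG input and output, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    tiff,
    png,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
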