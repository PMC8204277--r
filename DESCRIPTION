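Package: slimaps
Title: Fiber Direction Parameter Maps from Scattered Light Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-pixel analysis of azimuthal light-intensity profiles from
    scattered light imaging (SLI) stacks of brain sections. Detects periodic
    peaks on circular profiles, computes prominences, widths and sub-step
    corrected peak positions, reconstructs up to three crossing in-plane
    nerve-fiber directions per pixel, and assembles whole-image parameter
    maps (average intensity, peak counts, prominence, width, peak distance,
    directions). Includes a synthetic phantom generator with known ground
    truth, cross-technique comparison utilities (scatterometry line
    profiles, reference direction maps, scattering-pattern post-processing)
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    grDevices,
    graphics,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
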