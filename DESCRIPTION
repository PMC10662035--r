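Package: braggrass
Title: Bragg Reflection and Self-Organized Pattern Formation in Wave-Exposed
    Seagrass Meadows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the coupled dynamics of surface gravity waves and
    seagrass-built seabed topography in one horizontal dimension. Provides
    linear wave theory primitives (dispersion, shoaling, near-bed orbital
    kinematics, bed shear stress), wave-climate analysis that relates the
    most energetic waves to observed seagrass pattern wavelengths, a solver
    for the spatially uniform meadow equilibrium and its transcritical
    bifurcation under increasing wave forcing, a pseudo-spectral simulator of
    linearized wave scattering over a growing seagrass bed with absorbing
    sponge layers, and diagnostics for pattern spectra, modulation-instability
    thresholds and Bragg reflection coefficients. Synthetic generators for
    wave-climate series and pattern observations make every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
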