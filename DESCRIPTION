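Package: annulight
Title: Annular Irradiance and Diffuse Attenuation of Underwater Light
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the annular-irradiance approach to underwater
    radiometry: quad-based integration of the underwater radiance
    distribution into planar downwelling irradiance (Ed) and annular
    irradiances (Ea) over ring-shaped angular bands, PAR integration,
    diffuse attenuation coefficients (Kd, Ka) by the two-depth formula and
    by log-linear regression, and a simulation-grid assessment of how well
    Ka-derived estimates recover Kd across water types, solar zenith
    angles and cloud cover. Includes a parametric bio-optical model and a
    deterministic synthetic radiance generator that emulates the structure
    of radiative-transfer output (sun-peaked direct lobe inside Snell's
    window, refraction-compressed diffuse background, near-exponential
    decay) for testing and sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
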