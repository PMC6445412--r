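Package: retdefocus
Title: Retinal Defocus Pattern Maps from Scenes, Peripheral Refraction and
    Multifocal Contact Lenses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds per-condition retinal defocus maps for a right eye by
    combining environment dioptric-defocus maps over the central 40 degrees of
    visual field, individually measured peripheral-refraction shells (five
    horizontal meridians, repeated Hartmann-Shack scans), and multifocal
    contact-lens power profiles obtained by over-refraction subtraction.
    Classifies peripheral-refraction profiles (nasal/temporal positively
    skewed, relative peripheral myopia/hyperopia), interpolates 400x400
    dioptric field maps, segments maps into 5-degree eccentricity rings
    crossed with quadrant sectors, and compares regions across scenes,
    optical treatments and profile types with Kruskal-Wallis tests,
    rank-based familywise-error post-hoc comparisons, Mann-Whitney U tests
    and Benjamini-Hochberg false-discovery-rate control. Includes a
    synthetic-data generator for all three input classes so the full
    pipeline runs without access to clinical measurements.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
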