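Package: vagusmap
Title: Circular Co-Registration and Atlas Mapping of Vagus Nerve Fascicles
    and Spatially Selective Stimulation Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping the functional organization of a peripheral
    nerve cross-section from two complementary data streams: fascicle
    centroids traced from micro-computed tomography, and physiological
    responses (heart rate, breathing rate, end-tidal CO2, laryngeal EMG)
    elicited by spatially selective stimulation through a multi-pair cuff
    electrode. Fascicles are co-registered onto a normalized circular
    cross-section anchored to the cuff, per-pair responses are
    back-projected onto angular sectors, per-animal maps are rotationally
    aligned to the cardiac efferent reference and averaged into
    cross-animal atlas maps, and the spatial organization is quantified
    with center-of-mass angular statistics (circular separations, ANOVA
    with multiple comparisons, area fractions and overlaps). A synthetic
    cohort generator with planted angular structure, a distance-decay
    recruitment model and a titration protocol provides ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
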