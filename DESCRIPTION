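Package: ewimap
Title: Electromechanical Wave Imaging Activation Mapping and ECGI Comparison
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for cardiac electromechanical
    wave imaging (EWI) and electrocardiographic imaging (ECGI). Provides a
    synthetic phantom generator (myocardial masks, geodesic wavefront
    activation fields, high-frame-rate incremental axial strain movies,
    beamformed RF frames, epicardial unipolar electrograms), RF-based
    displacement and strain estimation, zero-crossing detection of
    electromechanical activation, Delaunay-based isochrone interpolation,
    multi-view co-registration and transmural site-of-origin localization,
    unipolar-electrogram analysis (beat averaging, maximum negative dV/dt
    local activation time, QS/rS morphology, slew rate), a biventricular
    24-segment bullseye model, electromechanical-delay statistics with
    subgroup ANOVA, and localization-accuracy scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    igraph,
    deldir,
    signal,
    rhdf5,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'utils.R'
    'geometry.R'
    'mask.R'
    'activation.R'
    'egm.R'
    'segments.R'
    'bullseye.R'
    'emd.R'
    'zc.R'
    'ecgi-synth.R'
    'strain-synth.R'
    'cohort.R'
    'rf-synth.R'
    'displacement.R'
    'ewimap-package.R'
    'io.R'
    'isochrone.R'
    'score.R'
    'pipeline.R'
    'plot.R'
    'register.R'
    'sampling.R'
    'show-methods.R'
    'soo.R'
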