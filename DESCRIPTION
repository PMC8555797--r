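Package: actimetrics
Title: Rest-Activity Rhythm and Sleep Analysis for Actigraphy Count Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing wrist-actigraphy activity-count recordings in
    circadian rhythm and sleep research. Provides a uniform epoch-series data
    model with readers for a canonical CSV dialect and AWD-style plaintext,
    start/stop-time logs and sleep diaries; masking of spurious inactivity;
    mean daily activity profiles with activity onset/offset estimation;
    non-parametric rest-activity rhythm variables (IS, IV, ISm, IVm, M10, L5,
    RA) with interval-wise computation; rest-to-activity transition
    probabilities (kRA, kAR) from run-length hazard estimates; epoch-by-epoch
    sleep scoring (Cole-Kripke, Sadeh, Scripps, Oakley) and consolidated rest
    period detection (Crespo, Roenneberg) with the sleep regularity index and
    sleep midpoint; and advanced signal analyses: cosinor rhythmometry,
    (multifractal) detrended fluctuation analysis, functional representations
    of daily profiles, locomotor-inactivity-during-sleep (LIDS) ultradian
    analysis, and singular spectrum analysis. Includes seeded synthetic-data
    generators with analytically known answers for validation.
License: MIT + file LICENSE
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    splines,
    xml2,
    yaml
Encoding: UTF-8
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
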