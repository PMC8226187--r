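Package: duetphase
Title: Simulation and Multi-Layer Analysis of Dyadic Phasing Performances
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying interpersonal coordination in duet music
    performance built around Steve Reich's phasing paradigm. Provides a
    synthetic performance generator (note onsets on a stable/accelerating
    bar schedule, beat-locked head motion, gaze, chair-pressure sway and
    pupil traces), a Kuramoto-model virtual partner with a tempo attractor,
    and three analysis layers: performance output (inter-onset intervals,
    cycle phase, relative phase, windowed synchronization index, joint
    recurrence quantification), embodied co-regulation (head-movement
    principal components, Morlet wavelet coherence with circular phase
    statistics, gaze angle, postural-sway recurrence plots), and subjective
    experience (questionnaire scoring, pupil normalization). Standard MIDI
    files, motion TSV, annotation CSV and JSON configs are the on-disk
    interfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
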